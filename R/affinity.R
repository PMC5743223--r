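#' Perplexity-calibrated conditional Gaussian affinities
#'
#' For each clone i, conditional neighbour probabilities over the other
#' clones are defined by an isotropic Gaussian kernel on the log-yield
#' vectors,
#' \deqn{P_{j|i} = \exp(-\|x_i - x_j\|^2 / 2\sigma_i^2) /
#'       \sum_{k \ne i} \exp(-\|x_i - x_k\|^2 / 2\sigma_i^2),}
#' with \eqn{P_{i|i} = 0} and the bandwidth \eqn{\sigma_i} calibrated per
#' row by binary search so that the perplexity (2 to the Shannon entropy)
#' of row i equals the requested perplexity — the effective neighbourhood
#' size.
#'
#' @param x N x d numeric matrix (typically log10-transformed,
#'   lineage-equalized yields); N >= 3.
#' @param perplexity target perplexity, must be < N.
#' @param tol convergence tolerance on |log2 achieved - log2 target|.
#' @param max_iter binary-search iteration cap per row.
#' @return List of class `clone_affinity`: `P` (N x N, rows sum to 1,
#'   zero diagonal), `sigma`, `perplexity`, `failed` (row indices whose
#'   search did not converge, e.g. rows at zero distance from all
#'   others).
#' @export
conditional_affinities <- function(x, perplexity, tol = 1e-5,
                                   max_iter = 200L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) abort("Need at least 3 points.")
  if (!is.finite(perplexity) || perplexity <= 1 || perplexity >= n) {
    abort("`perplexity` must lie in (1, N).")
  }
  d2 <- squared_distances(x)
  P <- matrix(0, n, n)
  sigma <- numeric(n)
  failed <- integer(0)
  log2u <- log2(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    if (all(di == 0)) {
      failed <- c(failed, i)
      P[i, -i] <- 1 / (n - 1)
      sigma[i] <- NA_real_
      next
    }
    # binary search on precision beta = 1 / (2 sigma^2)
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    p <- NULL
    ok <- FALSE
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { # beta too large
        beta_hi <- beta; beta <- (beta + beta_lo) / 2
        if (!is.finite(beta_lo)) beta <- beta_hi / 2
        next
      }
      p <- w / sw
      h <- -sum(ifelse(p > 0, p * log2(p), 0))
      diff <- h - log2u
      if (abs(diff) < tol) { ok <- TRUE; break }
      if (diff > 0) {       # entropy too high -> narrow kernel
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    if (!ok) failed <- c(failed, i)
    P[i, -i] <- p
    sigma[i] <- sqrt(1 / (2 * beta))
  }
  if (length(failed) > 0) {
    warn(paste0("Bandwidth search did not converge for row(s): ",
                paste(head(failed, 10), collapse = ", "),
                if (length(failed) > 10) " ..." else ""))
  }
  structure(list(P = P, sigma = sigma, perplexity = perplexity,
                 failed = failed),
            class = "clone_affinity")
}

#' Symmetrized joint affinities
#'
#' Converts conditional affinities into the symmetric joint distribution
#' \deqn{P(i,j) = (P_{j|i} + P_{i|j}) / (2N),} which sums to 1 over all
#' ordered pairs and can be read as the transition kernel of a diffusion
#' process over clones.
#'
#' @param cond a `clone_affinity` object or the conditional N x N matrix
#'   itself (rows summing to 1, zero diagonal).
#' @return Matrix of class `affinity_matrix` with attributes `sigma` and
#'   `perplexity` when available.
#' @export
joint_affinities <- function(cond) {
  P <- if (inherits(cond, "clone_affinity")) cond$P else as.matrix(cond)
  n <- nrow(P)
  stopifnot(n == ncol(P))
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8)) {
    abort("Conditional rows must each sum to 1.")
  }
  J <- (P + t(P)) / (2 * n)
  diag(J) <- 0
  attr(J, "sigma") <- if (inherits(cond, "clone_affinity")) cond$sigma
  attr(J, "perplexity") <- if (inherits(cond, "clone_affinity")) cond$perplexity
  class(J) <- c("affinity_matrix", class(J))
  J
}

squared_distances <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}
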