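#' Exact-gradient t-SNE embedding of an affinity matrix
#'
#' Minimizes the Kullback-Leibler divergence between the joint input
#' affinities P and a Student-t (one degree of freedom) kernel Q over
#' 2-D coordinates, by gradient descent with momentum, per-parameter
#' gain adaptation and an early-exaggeration phase. Gradients are exact
#' (O(N^2)); no tree approximation is used, which is immaterial at the
#' problem sizes of clonal assays (N of a few thousand at most).
#'
#' @param P an `affinity_matrix` from [joint_affinities()] (symmetric,
#'   zero diagonal, total mass 1).
#' @param seed integer; the random initial configuration (and hence the
#'   map) is fully reproducible given it.
#' @param n_iter gradient iterations.
#' @param learning_rate step size.
#' @param exaggeration,exaggeration_iter early-exaggeration factor and
#'   its duration.
#' @param momentum,final_momentum,momentum_switch momentum schedule.
#' @return Object of class `clone_tsne`: `coords` (N x 2), `kl_initial`,
#'   `kl_final`, `trace` (tibble iteration/kl), `seed`, plus the
#'   hyper-parameters.
#' @export
embed_tsne <- function(P, seed = 1L, n_iter = 1000L, learning_rate = 200,
                       exaggeration = 12, exaggeration_iter = 250L,
                       momentum = 0.5, final_momentum = 0.8,
                       momentum_switch = 250L) {
  P <- as.matrix(P)
  n <- nrow(P)
  stopifnot(n == ncol(P), n >= 2)
  if (max(abs(P - t(P))) > 1e-10 || any(diag(P) != 0) || any(P < 0)) {
    abort("P must be symmetric and non-negative with a zero diagonal.")
  }
  tot <- sum(P)
  if (abs(tot - 1) > 1e-8) abort("P must sum to 1.")
  eps <- 1e-12
  Pm <- pmax(P, eps)
  # exaggeration must end before the run does, or the map is left
  # optimized for the inflated objective
  exaggeration_iter <- min(exaggeration_iter, floor(n_iter / 2))
  momentum_switch <- min(momentum_switch, exaggeration_iter)

  withr::local_seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  kl_of <- function(Y) {
    Q <- student_q(Y)
    sum(P * (log(Pm) - log(pmax(Q$Q, eps))))
  }
  kl_initial <- kl_of(Y)

  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  trace_it <- integer(0); trace_kl <- numeric(0)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exaggeration_iter) P * exaggeration else P
    q <- student_q(Y)
    W <- (Pe - q$Q) * q$num        # (p - q) * (1 + d^2)^-1
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    if (any(!is.finite(grad))) {
      abort(paste0("Non-finite t-SNE gradient at iteration ", it, "."))
    }
    mom <- if (it <= momentum_switch) momentum else final_momentum
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- mom * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it %% 50 == 0 || it == n_iter) {
      trace_it <- c(trace_it, it)
      trace_kl <- c(trace_kl, kl_of(Y))
    }
  }
  kl_final <- kl_of(Y)
  structure(list(coords = Y, kl_initial = kl_initial, kl_final = kl_final,
                 trace = tibble(iteration = trace_it, kl = trace_kl),
                 seed = as.integer(seed), n_iter = n_iter,
                 learning_rate = learning_rate,
                 perplexity = attr(P, "perplexity")),
            class = "clone_tsne")
}

# Student-t kernel: num = (1 + d^2)^-1 with zero diagonal, Q = num/sum(num)
student_q <- function(Y) {
  d2 <- squared_distances(Y)
  num <- 1 / (1 + d2)
  diag(num) <- 0
  s <- sum(num)
  list(Q = if (s > 0) num / s else num, num = num)
}

#' Embed a clone table with the affinity + t-SNE pipeline
#'
#' Convenience wrapper chaining the standard preprocessing and
#' embedding: restrict to productive clones, optionally divide by donor
#' size factors, equalize lineage geometric means, log10(x+1) transform,
#' calibrate Gaussian affinities at the requested perplexity,
#' symmetrize, and run exact t-SNE.
#'
#' @param table a clone table.
#' @param thresholds positivity thresholds.
#' @param perplexity target perplexity (default 20).
#' @param donor_normalize,lineage_normalize toggle the two size-factor
#'   steps.
#' @param pseudocount for the log10 transform.
#' @param seed,n_iter passed to [embed_tsne()].
#' @return A `clone_tsne` object whose `clone_id` field aligns rows of
#'   `coords` with the productive clones.
#' @export
embed_clones <- function(table, thresholds = positivity_thresholds(),
                         perplexity = 20, donor_normalize = TRUE,
                         lineage_normalize = TRUE, pseudocount = 1,
                         seed = 1L, n_iter = 1000L) {
  table <- validate_clone_table(table)
  pos <- call_positivity(table, thresholds)
  keep <- pos$productive
  tab <- table[keep, , drop = FALSE]
  if (donor_normalize) tab <- apply_donor_size_factors(tab)
  m <- as.matrix(as.data.frame(tab)[, lineage_names(), drop = FALSE])
  rownames(m) <- tab$clone_id
  if (lineage_normalize) m <- lineage_size_factors(m, pseudocount)$scaled
  x <- log10_transform(m, pseudocount)
  P <- joint_affinities(conditional_affinities(x, perplexity))
  emb <- embed_tsne(P, seed = seed, n_iter = n_iter)
  emb$clone_id <- tab$clone_id
  emb$input <- x
  emb
}
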