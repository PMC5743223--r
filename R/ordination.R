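#' Principal component analysis of clone outputs
#'
#' Centered, unit-scaled PCA (i.e. on the correlation structure) via
#' `stats::prcomp`. Constant columns cannot be scaled and are dropped
#' with a warning.
#'
#' @param x numeric matrix, >= 2 rows and columns.
#' @return List of class `clone_pca`: `scores`, `loadings`,
#'   `variance_fraction`, `dropped`.
#' @export
pca_scores <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) abort("Need >= 2 rows and >= 2 columns.")
  const <- apply(x, 2, function(v) sd(v) == 0 || !all(is.finite(v)))
  dropped <- colnames(x)[const]
  if (any(const)) {
    warn(paste0("Dropping constant/non-finite column(s): ",
                paste(dropped, collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    if (ncol(x) < 2) abort("Fewer than 2 usable columns after dropping.")
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf, dropped = dropped),
            class = "clone_pca")
}

#' Spearman co-ancestry distances between lineages (or clones)
#'
#' Ancestral similarity between two lineages is the Spearman rank
#' correlation of their yields across all productive clones (average
#' ranks for ties); distance is `d = 1 - rho`, in `[0, 2]`. Transposing
#' the matrix gives the analogous potency distance between clones.
#'
#' @param table a clone table (>= 3 productive clones), or a numeric
#'   matrix whose columns are to be correlated.
#' @param thresholds positivity thresholds (clone-table input only).
#' @param transpose correlate clones (rows) instead of lineages.
#' @return Symmetric distance matrix (class `ancestry_distance`) with a
#'   `rho` attribute; pairs involving a constant column are `NA` and
#'   reported via a warning.
#' @export
lineage_ancestry_distance <- function(table,
                                      thresholds = positivity_thresholds(),
                                      transpose = FALSE) {
  if (is.data.frame(table)) {
    table <- validate_clone_table(table)
    pos <- call_positivity(table, thresholds)
    m <- clone_matrix(table)[pos$productive, , drop = FALSE]
  } else {
    m <- as.matrix(table)
  }
  if (transpose) m <- t(m)
  if (nrow(m) < 3) abort("Need at least 3 observations.")
  const <- apply(m, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  if (any(const)) {
    warn(paste0("Constant column(s), rho undefined for their pairs: ",
                paste(colnames(m)[const], collapse = ", ")))
  }
  d <- 1 - rho
  diag(d) <- 0
  attr(d, "rho") <- rho
  class(d) <- c("ancestry_distance", class(d))
  d
}

#' Classical multidimensional scaling
#'
#' Classical (Torgerson) MDS via `stats::cmdscale` with `eig = TRUE`:
#' double-center `-1/2 J D^2 J`, eigendecompose, and return the top-k
#' coordinates scaled by the square root of the eigenvalues. Negative
#' eigenvalues are returned — a `1 - rho` matrix need not be Euclidean.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k embedding dimension (default 2).
#' @return List of class `clone_mds`: `points` (N x k), `eig`,
#'   `k_effective` (positive eigenvalues actually available); columns
#'   beyond `k_effective` are zero-filled with a warning.
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    abort("D must be symmetric with a zero diagonal.")
  }
  n <- nrow(D)
  stopifnot(k >= 1, k <= n - 1)
  fit <- cmdscale(D, k = k, eig = TRUE)
  pts <- fit$points
  k_eff <- ncol(pts)
  if (is.null(pts) || k_eff < k) {
    warn(paste0("Only ", k_eff, " positive eigenvalue(s); ",
                "remaining coordinate(s) zero-filled."))
    filled <- matrix(0, n, k)
    if (k_eff > 0) filled[, seq_len(k_eff)] <- pts
    rownames(filled) <- rownames(D)
    pts <- filled
  }
  structure(list(points = pts, eig = fit$eig, k = k, k_effective = k_eff),
            class = "clone_mds")
}
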