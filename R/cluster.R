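#' Complete-linkage hierarchical clustering of clone outputs
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' via `stats::hclust` (ties resolved by the agglomeration order of
#' `hclust`, which is deterministic for a given input order). Complete
#' linkage guarantees monotone merge heights.
#'
#' @param x N x d numeric matrix (typically log10-scaled normalized
#'   yields), N >= 2; finite entries required.
#' @return An `hclust` object.
#' @export
hcluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("Need at least 2 rows.")
  if (!all(is.finite(x))) abort("Non-finite entries in clustering input.")
  hclust(dist(x, method = "euclidean"), method = "complete")
}

#' Cut a dendrogram into k clusters
#'
#' @param tree an `hclust` object.
#' @param k number of clusters, `1 <= k <= N`.
#' @return Integer vector of cluster labels.
#' @export
cut_k <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  stopifnot(k >= 1, k <= n)
  cutree(tree, k = k)
}

#' Optimal leaf ordering of a dendrogram
#'
#' Reorders the leaves of a hierarchical tree to maximize the sum of
#' similarities between adjacent leaves, over all 2^(N-1) subtree flips,
#' while keeping the tree topology unchanged (the Bar-Joseph dynamic
#' program). By default the similarity is the negative Euclidean
#' distance that built the tree; any symmetric similarity matrix aligned
#' with the leaves can be supplied.
#'
#' @param tree an `hclust` object.
#' @param S N x N symmetric similarity matrix aligned with the rows that
#'   were clustered (larger = more similar).
#' @return List of class `leaf_order`: `order` (leaf permutation),
#'   `objective` (achieved sum of adjacent similarities), `labels`.
#' @export
optimal_leaf_order <- function(tree, S) {
  stopifnot(inherits(tree, "hclust"))
  S <- as.matrix(S)
  n <- length(tree$order)
  if (!all(dim(S) == n)) abort("`S` must be N x N, aligned with the leaves.")
  if (max(abs(S - t(S))) > 1e-8) abort("`S` must be symmetric.")
  if (n == 1) {
    return(structure(list(order = 1L, objective = 0, labels = tree$labels),
                     class = "leaf_order"))
  }
  merge <- tree$merge

  leaves_of <- vector("list", nrow(merge))
  node_leaves <- function(id) {
    if (id < 0) return(-id)
    leaves_of[[id]]
  }
  for (v in seq_len(nrow(merge))) {
    leaves_of[[v]] <- c(node_leaves(merge[v, 1]), node_leaves(merge[v, 2]))
  }

  # M[[v]]: cost matrix over (leftmost, rightmost) leaves of node v;
  # bt stores the boundary pair (m, k) chosen at v for each (l, r).
  M <- vector("list", nrow(merge))
  BTm <- vector("list", nrow(merge))
  BTk <- vector("list", nrow(merge))
  get_M <- function(id) {
    if (id < 0) {
      m <- matrix(0, 1, 1, dimnames = list(-id, -id))
      return(m)
    }
    M[[id]]
  }
  for (v in seq_len(nrow(merge))) {
    A <- node_leaves(merge[v, 1]); B <- node_leaves(merge[v, 2])
    MA <- get_M(merge[v, 1]); MB <- get_M(merge[v, 2])
    SA <- S[A, B, drop = FALSE]
    # T[m, r] = max_k SA[m, k] + MB[k, r]; K[m, r] = argmax k
    Tm <- matrix(-Inf, length(A), length(B))
    K <- matrix(NA_integer_, length(A), length(B))
    for (r in seq_along(B)) {
      cand <- SA + matrix(MB[, r], length(A), length(B), byrow = TRUE)
      K[, r] <- max.col(cand, ties.method = "first")
      Tm[, r] <- cand[cbind(seq_along(A), K[, r])]
    }
    # Mv[l, r] = max_m MA[l, m] + T[m, r]
    nl <- length(A) + length(B)
    all_lv <- c(A, B)
    Mv <- matrix(-Inf, nl, nl, dimnames = list(all_lv, all_lv))
    btm <- btk <- matrix(NA_integer_, nl, nl)
    for (r in seq_along(B)) {
      cand <- MA + matrix(Tm[, r], length(A), length(A), byrow = TRUE)
      mi <- max.col(cand, ties.method = "first")
      val <- cand[cbind(seq_along(A), mi)]
      Mv[seq_along(A), length(A) + r] <- val
      btm[seq_along(A), length(A) + r] <- A[mi]
      btk[seq_along(A), length(A) + r] <- B[K[cbind(mi, r)]]
      # mirror orientation (subtree reversal has equal objective)
      Mv[length(A) + r, seq_along(A)] <- val
      btm[length(A) + r, seq_along(A)] <- A[mi]
      btk[length(A) + r, seq_along(A)] <- B[K[cbind(mi, r)]]
    }
    M[[v]] <- Mv; BTm[[v]] <- btm; BTk[[v]] <- btk
  }

  root <- nrow(merge)
  Mr <- M[[root]]
  best <- which(Mr == max(Mr), arr.ind = TRUE)[1, ]
  l_best <- as.integer(rownames(Mr)[best[1]])
  r_best <- as.integer(colnames(Mr)[best[2]])

  expand <- function(id, l, r) {
    if (id < 0) return(-id)
    A <- node_leaves(merge[id, 1]); B <- node_leaves(merge[id, 2])
    all_lv <- c(A, B)
    li <- match(l, all_lv); ri <- match(r, all_lv)
    m <- BTm[[id]][li, ri]; k <- BTk[[id]][li, ri]
    if (l %in% A) {
      c(expand(merge[id, 1], l, m), expand(merge[id, 2], k, r))
    } else {
      c(expand(merge[id, 2], l, k), expand(merge[id, 1], m, r))
    }
  }
  ord <- expand(root, l_best, r_best)
  structure(list(order = ord, objective = max(Mr), labels = tree$labels),
            class = "leaf_order")
}

#' Serialize a dendrogram as Newick
#'
#' @param tree an `hclust` object.
#' @param digits significant digits for branch lengths.
#' @return A single Newick string with merge-height branch lengths.
#' @export
hclust_newick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "hclust"))
  labs <- tree$labels %||% as.character(seq_along(tree$order))
  rec <- function(id, parent_h) {
    if (id < 0) {
      return(paste0(labs[-id], ":", signif(parent_h, digits)))
    }
    h <- tree$height[id]
    paste0("(", rec(tree$merge[id, 1], h), ",",
           rec(tree$merge[id, 2], h), "):",
           signif(parent_h - h, digits))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", rec(tree$merge[root, 1], h), ",",
         rec(tree$merge[root, 2], h), ");")
}
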