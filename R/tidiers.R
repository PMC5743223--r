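#' Tidiers for clonepotency result objects
#'
#' `tidy()` returns the per-observation table of a result; `glance()`
#' returns its one-row summary, in the broom idiom.
#'
#' @param x a result object.
#' @param ... unused.
#' @name clonepotency-tidiers
NULL

#' @rdname clonepotency-tidiers
#' @export
tidy.clone_tsne <- function(x, ...) {
  tibble(clone_id = x$clone_id %||% as.character(seq_len(nrow(x$coords))),
         dim1 = x$coords[, 1], dim2 = x$coords[, 2])
}

#' @rdname clonepotency-tidiers
#' @export
glance.clone_tsne <- function(x, ...) {
  tibble(n = nrow(x$coords), kl_initial = x$kl_initial,
         kl_final = x$kl_final, n_iter = x$n_iter, seed = x$seed,
         perplexity = x$perplexity %||% NA_real_)
}

#' @rdname clonepotency-tidiers
#' @export
tidy.clone_mds <- function(x, ...) {
  tibble(label = rownames(x$points) %||%
           as.character(seq_len(nrow(x$points))),
         dim1 = x$points[, 1], dim2 = x$points[, 2])
}

#' @rdname clonepotency-tidiers
#' @export
glance.clone_mds <- function(x, ...) {
  tibble(n = nrow(x$points), k = x$k, k_effective = x$k_effective,
         negative_eigenvalues = sum(x$eig < -1e-9),
         gof = sum(pmax(x$eig, 0)[seq_len(x$k)]) / sum(abs(x$eig)))
}

#' @rdname clonepotency-tidiers
#' @export
tidy.clone_pca <- function(x, ...) {
  as_tibble(x$scores, rownames = "row")
}

#' @rdname clonepotency-tidiers
#' @export
glance.clone_pca <- function(x, ...) {
  tibble(n_components = length(x$variance_fraction),
         pc1_variance = x$variance_fraction[1],
         pc2_variance = if (length(x$variance_fraction) > 1)
           x$variance_fraction[2] else NA_real_,
         dropped = length(x$dropped))
}

#' @rdname clonepotency-tidiers
#' @export
tidy.dosage_correlation <- function(x, ...) {
  as_tibble(x$r, rownames = "gate") |>
    tidyr::pivot_longer(-"gate", names_to = "lineage", values_to = "r") |>
    dplyr::left_join(
      as_tibble(x$p, rownames = "gate") |>
        tidyr::pivot_longer(-"gate", names_to = "lineage",
                            values_to = "p_value"),
      by = c("gate", "lineage"))
}

#' @rdname clonepotency-tidiers
#' @export
glance.dosage_correlation <- function(x, ...) {
  tibble(n_subsets = x$n, n_pairs = length(x$r),
         max_r = max(x$r, na.rm = TRUE),
         n_undefined = nrow(x$undefined), method = x$method)
}

#' @rdname clonepotency-tidiers
#' @export
tidy.inheritance_calls <- function(x, ...) as_tibble(x)

#' @rdname clonepotency-tidiers
#' @export
glance.inheritance_calls <- function(x, ...) {
  r <- inheritance_rate(x)
  tibble(n = r$n, inherited = r$inherited, switched = r$switched,
         rate = r$rate, se = r$se,
         n_families = dplyr::n_distinct(x$family_id))
}

#' @rdname clonepotency-tidiers
#' @export
tidy.potency_composition <- function(x, ...) x$composition

#' @rdname clonepotency-tidiers
#' @export
glance.potency_composition <- function(x, ...) {
  tibble(n_subsets = nrow(x$efficiency),
         seeded = sum(x$efficiency$seeded),
         productive = sum(x$efficiency$productive),
         overall_efficiency = sum(x$efficiency$productive) /
           sum(x$efficiency$seeded))
}
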