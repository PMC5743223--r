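#' Per-donor size factors within each progenitor subset
#'
#' Equalizes donors on the assumption that the geometric mean of total
#' clonal output for a given progenitor phenotype should be similar
#' across donors (the DESeq size-factor idea applied to clone totals).
#' For each subset, a donor's factor is the geometric mean of its clones'
#' total yields divided by the geometric mean of those per-donor
#' geometric means; dividing a clone's counts by its donor factor
#' equalizes per-donor geometric-mean totals within the subset.
#'
#' Zero-total (unproductive) clones are excluded from the geometric
#' means; a donor-subset group with only zero-yield clones gets factor
#' `NA`, is flagged, and is left unscaled with a warning.
#'
#' @param table a clone table.
#' @return Tibble: `subset`, `donor_id`, `factor`, `n_clones`, `flagged`.
#' @export
donor_size_factors <- function(table) {
  table <- validate_clone_table(table)
  m <- clone_matrix(table)
  tot <- rowSums(m)
  d <- tibble(subset = table$subset, donor_id = table$donor_id, total = tot)
  gm <- d |>
    dplyr::group_by(.data$subset, .data$donor_id) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      gmean = if (any(.data$total > 0))
        exp(mean(log(.data$total[.data$total > 0]))) else NA_real_,
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      factor = .data$gmean / exp(mean(log(.data$gmean[!is.na(.data$gmean)]))),
      flagged = is.na(.data$gmean)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("subset", "donor_id", "factor", "n_clones", "flagged")
  if (any(gm$flagged)) {
    warn(paste0(sum(gm$flagged),
                " donor-subset group(s) had only zero-yield clones; ",
                "their factors are NA and those clones are left unscaled."))
  }
  gm
}

#' Apply donor size factors to a clone table
#'
#' Divides each clone's lineage counts by its donor-within-subset factor.
#' The result is a numeric yield table (counts become positive reals);
#' per-clone ratios, and hence every bias statistic, are unchanged.
#'
#' @param table a clone table.
#' @param factors output of [donor_size_factors()]; computed from `table`
#'   when missing.
#' @return Tibble shaped like `table` with scaled lineage columns.
#' @export
apply_donor_size_factors <- function(table, factors = NULL) {
  table <- validate_clone_table(table)
  if (is.null(factors)) factors <- suppressWarnings(donor_size_factors(table))
  out <- as_tibble(unclass_clone(table))
  f <- factors$factor[match(paste(out$subset, out$donor_id),
                            paste(factors$subset, factors$donor_id))]
  f[is.na(f)] <- 1
  for (col in lineage_cols(out)) out[[col]] <- out[[col]] / f
  out
}

#' Per-lineage size factors
#'
#' Column scaling that equalizes the geometric mean yield of each lineage
#' across clones — the culture system under-produces some lineages (e.g.
#' pDC) and this removes that systematic depth difference before
#' embedding. With `pseudocount > 0` the geometric mean of
#' `x + pseudocount` is used over all clones; with `pseudocount = 0` the
#' geometric mean is taken over positive entries only (the DESeq-style
#' convention), which makes the factors exactly scale-equivariant.
#'
#' @param m clones x lineages count matrix (>= 2 columns).
#' @param pseudocount non-negative; default 1.
#' @return List: `factors` (named, mean-one in the geometric sense),
#'   `scaled` (matrix of `x / factor`), `flagged` (all-zero columns).
#' @export
lineage_size_factors <- function(m, pseudocount = 1) {
  m <- as.matrix(m)
  if (ncol(m) < 2) abort("Need at least two lineage columns.")
  stopifnot(pseudocount >= 0)
  all_zero <- colSums(m != 0) == 0
  gmean <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (pseudocount > 0) return(exp(mean(log(x + pseudocount))))
    if (all(x == 0)) return(NA_real_)
    exp(mean(log(x[x > 0])))
  }, numeric(1))
  names(gmean) <- colnames(m)
  gmean[all_zero] <- NA_real_
  if (any(all_zero)) {
    warn(paste0("All-zero lineage column(s): ",
                paste(colnames(m)[all_zero], collapse = ", "),
                "; factor undefined, left unscaled."))
  }
  fac <- gmean / exp(mean(log(gmean[!is.na(gmean)])))
  scaled <- sweep(m, 2, ifelse(is.na(fac), 1, fac), "/")
  list(factors = fac, scaled = scaled, flagged = colnames(m)[all_zero])
}

#' Elementwise log10 transform with pseudocount
#'
#' @param m numeric matrix of (normalized) counts.
#' @param pseudocount non-negative; must be positive if `m` contains
#'   zeros.
#' @return `log10(m + pseudocount)`.
#' @export
log10_transform <- function(m, pseudocount = 1) {
  m <- as.matrix(m)
  stopifnot(pseudocount >= 0)
  if (pseudocount == 0 && any(m <= 0)) {
    abort("Zeros present: log10_transform requires a positive pseudocount.")
  }
  log10(m + pseudocount)
}
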