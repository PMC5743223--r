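#' Lineage-positivity thresholds
#'
#' A lineage is called positive for a clone when its gate holds at least
#' the threshold number of events: 7 for every progenitor subset except
#' CDP, whose small clones are called at 2.
#'
#' @param default minimum events for non-CDP subsets.
#' @param overrides named integer vector of per-subset thresholds.
#' @return Named integer vector over all subsets.
#' @export
positivity_thresholds <- function(default = 7L, overrides = c(CDP = 2L)) {
  stopifnot(default >= 1, all(overrides >= 1))
  th <- setNames(rep(as.integer(default), length(subset_names())),
                 subset_names())
  th[names(overrides)] <- as.integer(overrides)
  th
}

#' Call lineage positivity per clone
#'
#' @param table a clone table.
#' @param thresholds named per-subset thresholds from
#'   [positivity_thresholds()].
#' @return Tibble: `clone_id`, `subset`, logical `pos_G ... pos_pDC`,
#'   `n_lineages`, `productive`.
#' @export
call_positivity <- function(table, thresholds = positivity_thresholds()) {
  table <- validate_clone_table(table)
  missing_th <- setdiff(unique(table$subset), names(thresholds))
  if (length(missing_th) > 0) {
    abort(paste0("No positivity threshold for subset(s): ",
                 paste(missing_th, collapse = ", ")))
  }
  m <- clone_matrix(table)
  th <- thresholds[table$subset]
  pos <- m >= th  # recycles th down each column: th is length N
  colnames(pos) <- paste0("pos_", lineage_names())
  dplyr::bind_cols(
    tibble(clone_id = table$clone_id, subset = table$subset),
    as_tibble(pos)
  ) |>
    dplyr::mutate(n_lineages = unname(rowSums(pos)),
                  productive = .data$n_lineages > 0)
}

#' Per-clone bias profiles
#'
#' For each productive clone: the commitment degree to each lineage
#' (lineage yield over total yield across the six lineages), the
#' equipotency ratio (smallest over largest yield among *positive*
#' lineages; 1 = truly equipotent; defined only for non-unipotent
#' clones), the bias ratio (second-largest over largest raw yield; 0 =
#' wholly biased; non-unipotent clones only) and the predominant lineage
#' (argmax yield, ties broken by canonical lineage order).
#'
#' All of these are ratios of within-clone yields and are therefore
#' invariant under any per-clone rescaling such as donor size-factor
#' normalization.
#'
#' @inheritParams call_positivity
#' @param equipotency_over `"positive"` (default) restricts the
#'   equipotency ratio to positive lineages; `"all"` uses all six yields
#'   (forcing 0 for any clone without six positive lineages).
#' @param keep_unproductive keep unproductive clones as all-`NA` profile
#'   rows instead of dropping them.
#' @return Tibble: `clone_id`, `donor_id`, `subset`, `division`,
#'   `total_yield`, `n_lineages`, `productive`, `cd_G ... cd_pDC`,
#'   `equipotency_ratio`, `bias_ratio`, `predominant`, `tie`.
#' @export
bias_profiles <- function(table, thresholds = positivity_thresholds(),
                          equipotency_over = c("positive", "all"),
                          keep_unproductive = FALSE) {
  equipotency_over <- match.arg(equipotency_over)
  table <- validate_clone_table(table)
  pos <- call_positivity(table, thresholds)
  m <- clone_matrix(table)
  lin <- lineage_names()
  posm <- as.matrix(pos[, paste0("pos_", lin)])
  total <- rowSums(m)
  cd <- m / ifelse(total > 0, total, NA_real_)
  colnames(cd) <- paste0("cd_", lin)

  n <- nrow(m)
  equi <- bias <- rep(NA_real_, n)
  predom <- rep(NA_character_, n)
  tie <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!pos$productive[i]) next
    y <- m[i, ]
    predom[i] <- lin[which.max(y)]  # which.max: first max = canonical order
    tie[i] <- sum(y == max(y)) > 1
    if (pos$n_lineages[i] >= 2) {
      yp <- if (equipotency_over == "positive") y[posm[i, ]] else y
      equi[i] <- min(yp) / max(yp)
      ys <- sort(y, decreasing = TRUE)
      bias[i] <- ys[2] / ys[1]
    }
  }
  out <- tibble(
    clone_id = table$clone_id, donor_id = table$donor_id,
    subset = table$subset, division = table$division,
    total_yield = total, n_lineages = pos$n_lineages,
    productive = pos$productive
  ) |>
    dplyr::bind_cols(as_tibble(cd)) |>
    dplyr::mutate(equipotency_ratio = equi, bias_ratio = bias,
                  predominant = predom, tie = tie)
  if (!keep_unproductive) out <- dplyr::filter(out, .data$productive)
  if (nrow(out) == 0) abort("No productive clones to profile.",
                            class = "clone_validation_error")
  if (any(out$tie)) {
    inform(paste0(sum(out$tie), " clone(s) had tied maximal yields; ",
                  "predominant lineage broken by canonical order."))
  }
  out
}

#' Per-subset potency composition
#'
#' Summarizes each progenitor subset: clonal efficiency (productive over
#' seeded wells), the distribution of the number of lineages produced,
#' and the bias-group composition (percentage of productive clones
#' predominant to each lineage) with the standard error of proportion
#' `sqrt(p (1 - p) / n)`.
#'
#' @inheritParams call_positivity
#' @return List of tibbles: `efficiency`, `n_lineage_dist`, `composition`
#'   (class `potency_composition`).
#' @export
potency_composition <- function(table, thresholds = positivity_thresholds()) {
  table <- validate_clone_table(table)
  prof <- bias_profiles(table, thresholds, keep_unproductive = TRUE)
  eff <- prof |>
    dplyr::group_by(.data$subset) |>
    dplyr::summarise(seeded = dplyr::n(),
                     productive = sum(.data$productive),
                     efficiency = .data$productive / .data$seeded,
                     se = sqrt(.data$efficiency * (1 - .data$efficiency) /
                                 .data$seeded),
                     .groups = "drop")
  nld <- prof |>
    dplyr::filter(.data$productive) |>
    dplyr::count(.data$subset, .data$n_lineages, name = "n_clones") |>
    dplyr::group_by(.data$subset) |>
    dplyr::mutate(fraction = .data$n_clones / sum(.data$n_clones)) |>
    dplyr::ungroup()
  comp <- prof |>
    dplyr::filter(.data$productive) |>
    dplyr::count(.data$subset,
                 lineage = factor(.data$predominant,
                                  levels = lineage_names()),
                 .drop = FALSE, name = "n_clones") |>
    dplyr::group_by(.data$subset) |>
    dplyr::mutate(n = sum(.data$n_clones),
                  proportion = .data$n_clones / .data$n,
                  percent = 100 * .data$proportion,
                  se = sqrt(.data$proportion * (1 - .data$proportion) /
                              .data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(lineage = as.character(.data$lineage))
  structure(list(efficiency = eff, n_lineage_dist = nld,
                 composition = comp),
            class = "potency_composition")
}

#' Bias-versus-yield association
#'
#' Frequency histograms (bin width 0.1) of the equipotency and bias
#' ratios of all non-unipotent clones, with the cumulative percentage of
#' clones below and above 0.5, and Spearman correlations of each ratio
#' against log10 total clonal yield.
#'
#' @param profiles output of [bias_profiles()] (>= 3 non-unipotent rows).
#' @return List (class `bias_yield_association`): `histograms` tibble
#'   (statistic, bin, n, fraction), `cumulative` tibble (statistic,
#'   pct_below_0.5, pct_above_0.5, n), `spearman` tibble (statistic, rho,
#'   p_value, degenerate).
#' @export
bias_yield_association <- function(profiles) {
  nu <- dplyr::filter(profiles, !is.na(.data$equipotency_ratio))
  if (nrow(nu) < 3) abort("Need at least 3 non-unipotent clones.")
  breaks <- seq(0, 1, by = 0.1)
  one <- function(x, label) {
    bin <- cut(x, breaks, include.lowest = TRUE, right = TRUE)
    h <- tibble(statistic = label, bin = levels(bin)) |>
      dplyr::left_join(tibble(bin = as.character(bin)) |>
                         dplyr::count(.data$bin),
                       by = "bin") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                    fraction = .data$n / length(x))
    cum <- tibble(statistic = label,
                  pct_below_0.5 = 100 * mean(x < 0.5),
                  pct_above_0.5 = 100 * mean(x > 0.5),
                  n = length(x))
    degenerate <- length(unique(nu$total_yield)) == 1 ||
      length(unique(x)) == 1
    if (degenerate) {
      sp <- tibble(statistic = label, rho = NA_real_, p_value = NA_real_,
                   degenerate = TRUE)
    } else {
      ct <- suppressWarnings(
        cor.test(x, log10(nu$total_yield), method = "spearman"))
      sp <- tibble(statistic = label, rho = unname(ct$estimate),
                   p_value = ct$p.value, degenerate = FALSE)
    }
    list(h = h, cum = cum, sp = sp)
  }
  eq <- one(nu$equipotency_ratio, "equipotency_ratio")
  br <- one(nu$bias_ratio, "bias_ratio")
  structure(list(
    histograms = dplyr::bind_rows(eq$h, br$h),
    cumulative = dplyr::bind_rows(eq$cum, br$cum),
    spearman = dplyr::bind_rows(eq$sp, br$sp)
  ), class = "bias_yield_association")
}
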