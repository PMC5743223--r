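#' Infer ancestor potency from granddaughter yields
#'
#' An ancestor's quantitative potency is the elementwise sum of its
#' granddaughters' yield vectors. Families with fewer than two viable
#' granddaughters are excluded (single-granddaughter ancestors carry no
#' inheritance information).
#'
#' @param family tibble of one family's granddaughters with lineage
#'   count columns.
#' @return Named integer vector of summed yields.
#' @export
infer_ancestor_potency <- function(family) {
  lin <- core_lineage_cols(family)
  if (length(lin) < 6) abort("Family lacks the six core lineage columns.")
  if (nrow(family) < 2) {
    abort("Ancestors with a single viable granddaughter are excluded.",
          class = "family_exclusion_error")
  }
  colSums(as.matrix(family[, lineage_names()]))
}

#' Classify bias inheritance across granddaughter families
#'
#' For every family: the ancestor's predominant lineage is taken from
#' the granddaughter sum; each productive granddaughter is classified as
#' bias-inherited (same predominant lineage as the ancestor) or
#' bias-switched, and its commitment fold-change is computed — the
#' granddaughter's commitment degree to its *own* predominant lineage
#' divided by the ancestor's commitment degree to that same lineage.
#' Unproductive granddaughters are dropped with a warning; families left
#' with fewer than two classified granddaughters are excluded.
#'
#' @param families long tibble from [simulate_granddaughter_families()]
#'   or read from file: `family_id`, `well_id`, optional `subset`, and
#'   the six lineage columns.
#' @param thresholds per-subset positivity thresholds; granddaughters are
#'   productive when any lineage reaches the threshold (default 7, the
#'   non-CDP rule, when no subset column is present).
#' @return Tibble of class `inheritance_calls`: one row per classified
#'   granddaughter with `family_id`, `well_id`, `subset`,
#'   `ancestor_bias`, `predominant`, `inherited`, `total_yield`,
#'   `commitment` (to its own predominant lineage), `fold_change`,
#'   `fold_change_defined`. Note the fold-change of a bias-switched
#'   granddaughter is taken against the ancestor's (typically small)
#'   commitment to the *new* lineage and is therefore often large; the
#'   commitment column is the right basis for comparing how committed
#'   inherited and switched progeny are.
#' @export
classify_inheritance <- function(families,
                                 thresholds = positivity_thresholds()) {
  lin <- lineage_names()
  stopifnot(all(c("family_id", "well_id", lin) %in% names(families)))
  if (!"subset" %in% names(families)) families$subset <- "HSC"
  m <- as.matrix(families[, lin])
  storage.mode(m) <- "double"
  th <- thresholds[families$subset]
  productive <- rowSums(m >= th) > 0
  if (any(!productive)) {
    warn(paste0(sum(!productive),
                " unproductive granddaughter(s) dropped before ",
                "classification."))
  }
  fam_split <- split(which(productive), families$family_id[productive])
  dropped_fams <- names(fam_split)[lengths(fam_split) < 2]
  if (length(dropped_fams) > 0) {
    warn(paste0(length(dropped_fams), " family(ies) with < 2 productive ",
                "granddaughters excluded."))
    fam_split <- fam_split[lengths(fam_split) >= 2]
  }
  if (length(fam_split) == 0) abort("No classifiable families.")
  calls <- purrr::map(fam_split, function(rows) {
    ym <- m[rows, , drop = FALSE]
    anc <- colSums(ym)
    anc_bias <- lin[which.max(anc)]
    anc_cd <- anc / sum(anc)
    gd_tot <- rowSums(ym)
    gd_pred <- lin[apply(ym, 1, which.max)]
    gd_cd_own <- ym[cbind(seq_len(nrow(ym)), match(gd_pred, lin))] / gd_tot
    anc_cd_own <- anc_cd[match(gd_pred, lin)]
    fc <- ifelse(anc_cd_own > 0, gd_cd_own / anc_cd_own, NA_real_)
    tibble(family_id = families$family_id[rows],
           well_id = families$well_id[rows],
           subset = families$subset[rows],
           ancestor_bias = anc_bias,
           predominant = gd_pred,
           inherited = gd_pred == anc_bias,
           total_yield = gd_tot,
           commitment = gd_cd_own,
           fold_change = fc,
           fold_change_defined = !is.na(fc))
  })
  out <- dplyr::bind_rows(calls)
  if (any(!out$fold_change_defined)) {
    warn("Some fold-changes undefined (ancestor commitment 0); flagged NA.")
  }
  class(out) <- unique(c("inheritance_calls", class(out)))
  out
}

#' Pooled inheritance rate with standard error
#'
#' @param calls an `inheritance_calls` tibble.
#' @param by optional grouping column (e.g. `"subset"`).
#' @return Tibble: `n`, `inherited`, `switched`, `rate`, `se` (standard
#'   error of proportion).
#' @export
inheritance_rate <- function(calls, by = NULL) {
  g <- if (is.null(by)) calls else dplyr::group_by(calls, .data[[by]])
  dplyr::summarise(g,
                   n = dplyr::n(),
                   n_inherited = sum(.data$inherited),
                   .groups = "drop") |>
    dplyr::mutate(inherited = .data$n_inherited,
                  switched = .data$n - .data$n_inherited,
                  rate = .data$inherited / .data$n,
                  se = sqrt(.data$rate * (1 - .data$rate) / .data$n)) |>
    dplyr::select(-"n_inherited")
}

#' Bias switch-direction matrix
#'
#' Entry (a, b) counts granddaughters whose ancestor was biased to
#' lineage a and who are themselves biased to lineage b; the diagonal
#' holds inherited counts, off-diagonals the switches. Row sums equal
#' the number of classified granddaughters per ancestor bias.
#'
#' @param calls an `inheritance_calls` tibble.
#' @return 6 x 6 integer matrix.
#' @export
switch_direction_matrix <- function(calls) {
  lin <- lineage_names()
  tab <- table(factor(calls$ancestor_bias, levels = lin),
               factor(calls$predominant, levels = lin))
  m <- matrix(as.integer(tab), 6, 6, dimnames = list(lin, lin))
  m
}

#' Commitment fold-change of one granddaughter
#'
#' @param ancestor,granddaughter named six-lineage yield vectors (both
#'   productive).
#' @return The granddaughter's commitment to its own predominant lineage
#'   divided by the ancestor's commitment to that lineage (`NA` with a
#'   warning when the ancestor commitment is 0).
#' @export
commitment_fold_change <- function(ancestor, granddaughter) {
  lin <- lineage_names()
  if (is.null(names(ancestor))) names(ancestor) <- lin
  if (is.null(names(granddaughter))) names(granddaughter) <- lin
  ancestor <- ancestor[lin]; granddaughter <- granddaughter[lin]
  if (sum(granddaughter) == 0 || sum(ancestor) == 0) {
    abort("Both ancestor and granddaughter must be productive.")
  }
  own <- lin[which.max(granddaughter)]
  anc_cd <- ancestor[[own]] / sum(ancestor)
  if (anc_cd == 0) {
    warn("Ancestor commitment to the granddaughter's lineage is 0.")
    return(NA_real_)
  }
  (granddaughter[[own]] / sum(granddaughter)) / anc_cd
}

#' Sibling yield comparison: inherited vs switched
#'
#' Pairs, within each family containing both classes, the mean total
#' yield of bias-inheriting granddaughters against the mean of their
#' bias-switching siblings; families lacking one class are dropped.
#'
#' @param calls an `inheritance_calls` tibble.
#' @return Tibble: `family_id`, `mean_inherited`, `mean_switched`.
#' @export
sibling_yield_comparison <- function(calls) {
  calls |>
    dplyr::group_by(.data$family_id) |>
    dplyr::filter(any(.data$inherited) && any(!.data$inherited)) |>
    dplyr::summarise(
      mean_inherited = mean(.data$total_yield[.data$inherited]),
      mean_switched = mean(.data$total_yield[!.data$inherited]),
      .groups = "drop")
}
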