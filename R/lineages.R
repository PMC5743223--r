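#' Canonical lineage and progenitor-subset vocabularies
#'
#' The assay scores each clone's terminal output in six lineages:
#' granulocytes (G), monocytes (M), B/NK lymphocytes (L), CD141+
#' conventional dendritic cells (DC1), CD1c+ conventional dendritic cells
#' (DC2) and plasmacytoid dendritic cells (pDC). The erythrocyte (Er) and
#' megakaryocyte (Mk) columns appear only in tables from the
#' Er/Mk-supportive culture arm. One fixed column order is used everywhere
#' so that every downstream statistic is invariant to how an input file
#' happened to order its columns.
#'
#' @param extra if `TRUE`, append the optional Er/Mk lineages.
#' @return Character vector of lineage names in canonical order.
#' @export
#' @examples
#' lineage_names()
#' lineage_names(extra = TRUE)
lineage_names <- function(extra = FALSE) {
  core <- c("G", "M", "L", "DC1", "DC2", "pDC")
  if (extra) c(core, "Er", "Mk") else core
}

#' @rdname lineage_names
#' @export
subset_names <- function() {
  c("HSC", "MPP", "LMPP", "MLP", "BNKP", "CMP", "GMDP", "MDP", "CDP")
}

#' @rdname lineage_names
#' @export
culture_names <- function() {
  c("MPFSG", "JD")
}

# internal: lineage columns present in a table, canonical order first
lineage_cols <- function(df) {
  intersect(lineage_names(extra = TRUE), names(df))
}

core_lineage_cols <- function(df) {
  intersect(lineage_names(), names(df))
}
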