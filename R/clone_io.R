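#' Validate a clone table
#'
#' A clone table is a data frame with one row per single-cell-derived
#' clone: identity columns (`clone_id`, `donor_id`, `subset`, `culture`,
#' optional `division`) and one non-negative integer count column per
#' lineage. Validation canonicalizes the lineage column order
#' (G, M, L, DC1, DC2, pDC, then Er/Mk if present), coerces identity
#' columns to character/factor-free types and fails with row-indexed
#' diagnostics on malformed counts.
#'
#' @param df a data frame resembling a clone table.
#' @param column_map optional named character vector mapping the canonical
#'   column names (names of the vector) to the names used in `df`
#'   (values), for importing tables with a foreign layout, e.g.
#'   `c(clone_id = "well", G = "granulo")`.
#' @return A validated clone-table tibble (class `clone_table`), lineage
#'   columns in canonical order.
#' @export
validate_clone_table <- function(df, column_map = NULL) {
  stopifnot(is.data.frame(df))
  df <- as_tibble(df)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      abort("`column_map` must be a fully named character vector.")
    }
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src) > 0) {
      abort(paste0("`column_map` refers to absent columns: ",
                   paste(missing_src, collapse = ", ")))
    }
    idx <- match(unname(column_map), names(df))
    names(df)[idx] <- names(column_map)
  }

  mandatory <- c("clone_id", "donor_id", "subset", "culture")
  absent <- setdiff(mandatory, names(df))
  if (length(absent) > 0) {
    abort(paste0("Clone table is missing mandatory column(s): ",
                 paste(absent, collapse = ", ")), class = "clone_schema_error")
  }
  lin <- lineage_cols(df)
  if (length(intersect(lineage_names(), lin)) < length(lineage_names())) {
    abort(paste0("Clone table must contain all six core lineage columns (",
                 paste(lineage_names(), collapse = ", "), ")."),
          class = "clone_schema_error")
  }
  if (nrow(df) == 0) {
    abort("Clone table has no rows.", class = "clone_validation_error")
  }

  df$clone_id <- as.character(df$clone_id)
  df$donor_id <- as.character(df$donor_id)
  df$subset <- as.character(df$subset)
  df$culture <- as.character(df$culture)
  if (!"division" %in% names(df)) df$division <- NA_integer_

  bad_subset <- unique(df$subset[!df$subset %in% subset_names()])
  if (length(bad_subset) > 0) {
    abort(paste0("Unknown progenitor subset(s): ",
                 paste(bad_subset, collapse = ", ")),
          class = "clone_validation_error")
  }
  bad_culture <- unique(df$culture[!df$culture %in% culture_names()])
  if (length(bad_culture) > 0) {
    abort(paste0("Unknown culture system(s): ",
                 paste(bad_culture, collapse = ", ")),
          class = "clone_validation_error")
  }
  dup <- df$clone_id[duplicated(df$clone_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated clone_id(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "clone_validation_error")
  }

  for (col in lin) {
    x <- df[[col]]
    if (is.character(x)) {
      suppressWarnings(xn <- as.numeric(x))
    } else {
      xn <- as.numeric(x)
    }
    bad <- which(!is.finite(xn) | xn < 0 | xn != round(xn))
    if (length(bad) > 0) {
      abort(paste0("Lineage column `", col, "` has invalid counts at row(s) ",
                   paste(head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) " ..." else "",
                   " (counts must be non-negative integers)."),
            class = "clone_validation_error")
    }
    df[[col]] <- as.integer(round(xn))
  }
  if (!all(is.na(df$division))) {
    suppressWarnings(dv <- as.numeric(df$division))
    bad <- which((!is.na(df$division) & is.na(dv)) |
                   (!is.na(dv) & (dv < 0 | dv != round(dv))))
    if (length(bad) > 0) {
      abort(paste0("`division` must be a non-negative integer; bad row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "clone_validation_error")
    }
    df$division <- as.integer(dv)
  }

  meta <- c("clone_id", "donor_id", "subset", "culture", "division")
  df <- df[, c(meta, lin), drop = FALSE]
  class(df) <- unique(c("clone_table", class(df)))
  df
}

#' Read a delimited clone table
#'
#' @param path path to a CSV or TSV file with header columns `clone_id`,
#'   `donor_id`, `subset`, `culture`, optional `division`, and the lineage
#'   count columns `G, M, L, DC1, DC2, pDC` (optionally `Er`, `Mk`).
#' @param dialect `"csv"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @inheritParams validate_clone_table
#' @return A validated `clone_table` tibble with a `source` attribute.
#' @examples
#' path <- system.file("extdata", "synthetic_example_clones.csv",
#'                     package = "clonepotency")
#' read_clone_table(path)
#' @export
read_clone_table <- function(path, dialect = c("auto", "csv", "tsv"),
                             column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  out <- validate_clone_table(raw, column_map = column_map)
  attr(out, "source") <- path
  out
}

#' Write a clone table to CSV or TSV
#'
#' Columns are written in canonical order (identity columns, then G, M, L,
#' DC1, DC2, pDC, then Er/Mk if present); missing metadata are written as
#' empty cells so that `read_clone_table()` round-trips the table
#' field-for-field.
#'
#' @param table a validated clone table.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(table, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  table <- validate_clone_table(table)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(as_tibble(unclass_clone(table)), path, na = "", progress = FALSE)
  invisible(path)
}

# strip the clone_table class for plain-data operations
unclass_clone <- function(table) {
  class(table) <- setdiff(class(table), "clone_table")
  table
}

#' Extract the clone-by-lineage count matrix
#'
#' @param table a clone table.
#' @param extra include Er/Mk columns when present.
#' @return Integer matrix, rownames = `clone_id`, columns in canonical
#'   lineage order.
#' @export
clone_matrix <- function(table, extra = FALSE) {
  lin <- if (extra) lineage_cols(table) else core_lineage_cols(table)
  m <- as.matrix(as.data.frame(table)[, lin, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$clone_id
  m
}
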