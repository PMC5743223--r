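#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its
#' study-profile default: positivity thresholds 7 (2 for CDP),
#' perplexity 20, backbone commitment threshold 0.7, log pseudocount 1,
#' four-cluster cut. All stages derive their randomness from `seed`.
#'
#' @param input optional path to a clone table (CSV/TSV); when `NULL`,
#'   clones are simulated from `sim`.
#' @param sim a [sim_params()] object used when `input` is `NULL` (its
#'   seed is overridden by `seed`).
#' @param thresholds named per-subset positivity thresholds.
#' @param perplexity t-SNE perplexity.
#' @param backbone_threshold commitment threshold for track backbones.
#' @param pseudocount for the log10 transform.
#' @param k clusters for the dendrogram cut.
#' @param n_iter t-SNE iterations.
#' @param donor_normalize,lineage_normalize size-factor toggles.
#' @param n_families granddaughter families to simulate (synthetic runs).
#' @param dosage_noise_sd gate-percentage noise (synthetic runs).
#' @param olo_max_n optimal leaf ordering is applied to the clone
#'   dendrogram only up to this many clones (the lineage dendrogram is
#'   always ordered); the dynamic program is cubic in the leaf count.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_params(),
                            thresholds = positivity_thresholds(),
                            perplexity = 20, backbone_threshold = 0.7,
                            pseudocount = 1, k = 4, n_iter = 1000L,
                            donor_normalize = TRUE, lineage_normalize = TRUE,
                            n_families = 200L, dosage_noise_sd = 3,
                            olo_max_n = 400L, seed = 1L) {
  if (is.null(input) && is.null(sim)) {
    abort("Config needs either an `input` path or `sim` parameters.",
          class = "pipeline_config_error")
  }
  if (!is.null(input) && !file.exists(input)) {
    abort(paste0("Input file not found: ", input),
          class = "pipeline_config_error")
  }
  stopifnot(perplexity > 1, backbone_threshold > 0.5,
            backbone_threshold <= 1, pseudocount >= 0, k >= 1)
  structure(list(input = input, sim = sim, thresholds = thresholds,
                 perplexity = perplexity,
                 backbone_threshold = backbone_threshold,
                 pseudocount = pseudocount, k = as.integer(k),
                 n_iter = as.integer(n_iter),
                 donor_normalize = donor_normalize,
                 lineage_normalize = lineage_normalize,
                 n_families = as.integer(n_families),
                 dosage_noise_sd = dosage_noise_sd,
                 olo_max_n = as.integer(olo_max_n),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `sim:` entries
#' override [sim_params()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- lapply(y$sim %||% list(),
                     function(v) if (is.list(v)) unlist(v) else v)
  y$sim <- NULL
  sim <- do.call(sim_params, sim_args)
  do.call(pipeline_config, c(y, list(sim = sim)))
}

#' Run the full clonal-potency pipeline
#'
#' Orchestrates: clone acquisition (file or simulation), positivity and
#' bias profiling, per-subset composition, donor and lineage
#' normalization, affinity calibration and t-SNE embedding, backbone and
#' track assignment, complete-linkage clustering with a k-cluster cut
#' and optimal leaf ordering, lineage co-ancestry MDS, granddaughter
#' inheritance classification and dosage correlations (synthetic runs),
#' and a machine-readable manifest. Identical config and seed give
#' byte-identical artifacts.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of artifact paths plus the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  counts <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "pipeline_stage_error")
    })
  }

  # clones
  synthetic <- is.null(config$input)
  table <- stage("clones", {
    if (synthetic) {
      sim <- config$sim; sim$seed <- config$seed
      simulate_clone_table(sim)
    } else {
      read_clone_table(config$input)
    }
  })
  wr(as_tibble(unclass_clone(table)), "clone_table")
  counts$clones_in <- nrow(table)

  # profiles + composition
  prof <- stage("profiles",
                bias_profiles(table, config$thresholds,
                              keep_unproductive = TRUE))
  wr(prof, "profiles")
  comp <- stage("composition", potency_composition(table, config$thresholds))
  wr(comp$efficiency, "clonal_efficiency")
  wr(comp$composition, "bias_composition")
  counts$productive <- sum(prof$productive)

  # normalization factors
  dsf <- stage("donor_factors", suppressWarnings(donor_size_factors(table)))
  wr(dsf, "donor_size_factors")

  # embedding
  emb <- stage("embedding",
               embed_clones(table, config$thresholds,
                            perplexity = config$perplexity,
                            donor_normalize = config$donor_normalize,
                            lineage_normalize = config$lineage_normalize,
                            pseudocount = config$pseudocount,
                            seed = config$seed, n_iter = config$n_iter))
  emb_tb <- tibble(clone_id = emb$clone_id,
                   dim1 = emb$coords[, 1], dim2 = emb$coords[, 2])
  wr(emb_tb, "embedding")

  # tracks
  prod_prof <- dplyr::filter(prof, .data$productive)
  tracks <- stage("tracks",
                  assign_clone_tracks(prod_prof, emb,
                                      threshold = config$backbone_threshold))
  wr(tracks, "tracks")

  # clustering of the embedded input matrix
  clus <- stage("cluster", {
    x <- emb$input
    tree <- hcluster(x)
    labels <- cut_k(tree, min(config$k, nrow(x)))
    lin_tree <- hcluster(t(x))
    lin_S <- -as.matrix(dist(t(x)))
    lin_olo <- optimal_leaf_order(lin_tree, lin_S)
    clone_olo <- if (nrow(x) <= config$olo_max_n) {
      optimal_leaf_order(tree, -as.matrix(dist(x)))
    } else NULL
    list(tree = tree, labels = labels, lin_olo = lin_olo,
         clone_olo = clone_olo)
  })
  wr(tibble(clone_id = prod_prof$clone_id, cluster = clus$labels),
     "clusters")
  writeLines(hclust_newick(clus$tree),
             paths[["dendrogram"]] <- file.path(out_dir, "dendrogram.nwk"))
  wr(tibble(position = seq_along(clus$lin_olo$order),
            lineage = lineage_names()[clus$lin_olo$order]),
     "lineage_leaf_order")

  # co-ancestry MDS over lineages
  mds <- stage("mds", {
    d <- lineage_ancestry_distance(table, config$thresholds)
    fit <- classical_mds(d, k = 2)
    list(d = d, fit = fit)
  })
  wr(tibble(lineage = rownames(mds$fit$points),
            dim1 = mds$fit$points[, 1], dim2 = mds$fit$points[, 2]),
     "lineage_mds")

  # heritage + dosage (synthetic runs simulate their own inputs)
  heritage <- dosage <- NULL
  if (synthetic) {
    sim <- config$sim; sim$seed <- config$seed
    fams <- stage("heritage",
                  simulate_granddaughter_families(sim, config$n_families))
    calls <- stage("heritage",
                   suppressWarnings(
                     classify_inheritance(fams, config$thresholds)))
    wr(calls, "inheritance_calls")
    wr(inheritance_rate(calls), "inheritance_rate")
    heritage <- list(families = fams, calls = calls)
    counts$granddaughters_classified <- nrow(calls)

    dt <- stage("dosage", simulate_dosage_tables(sim, config$dosage_noise_sd))
    dcor <- stage("dosage", correlate_compositions(dt))
    wr(as_tibble(dcor$r, rownames = "gate"), "dosage_r")
    wr(as_tibble(dcor$p, rownames = "gate"), "dosage_p")
    dosage <- list(tables = dt, correlation = dcor)
  }

  # division summaries when any clone is division-tracked
  division <- NULL
  if (any(!is.na(table$division))) {
    division <- stage("division",
                      summarize_division_potency(table, config$thresholds))
    wr(division, "division_potency")
  }

  manifest <- list(
    package = "clonepotency",
    version = as.character(packageVersion("clonepotency")),
    seed = config$seed,
    synthetic = synthetic,
    config_hash = rlang::hash(config),
    counts = counts,
    kl = list(initial = emb$kl_initial, final = emb$kl_final),
    artifacts = sort(names(paths))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths$manifest <- mp

  invisible(list(paths = paths, table = table, profiles = prof,
                 composition = comp, embedding = emb, tracks = tracks,
                 cluster = clus, mds = mds, heritage = heritage,
                 dosage = dosage, division = division,
                 manifest = manifest))
}

#' Per-division clonal output summaries
#'
#' For division-tracked clones: per division level, the mean and
#' standard error (`sd/sqrt(n)`) of total clonal yield and the
#' composition of potency classes (number of lineages produced).
#'
#' @param table a clone table with a `division` column.
#' @param thresholds positivity thresholds.
#' @return Tibble keyed by `division` (empty, with a notice, when no
#'   clone is division-tracked).
#' @export
summarize_division_potency <- function(table,
                                       thresholds = positivity_thresholds()) {
  table <- validate_clone_table(table)
  tracked <- !is.na(table$division)
  if (!any(tracked)) {
    inform("No division-tracked clones; empty summary.")
    return(tibble(division = integer(0), n = integer(0),
                  mean_yield = numeric(0), sem_yield = numeric(0)))
  }
  prof <- bias_profiles(table[tracked, , drop = FALSE], thresholds,
                        keep_unproductive = TRUE)
  yield <- prof |>
    dplyr::group_by(division = .data$division) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_yield = mean(.data$total_yield),
                     sem_yield = sd(.data$total_yield) / sqrt(dplyr::n()),
                     productive = sum(.data$productive),
                     .groups = "drop")
  classes <- prof |>
    dplyr::filter(.data$productive) |>
    dplyr::count(division = .data$division, .data$n_lineages) |>
    dplyr::group_by(.data$division) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = "division",
                       names_from = "n_lineages",
                       names_prefix = "frac_lineages_",
                       values_from = "fraction", values_fill = 0)
  dplyr::left_join(yield, classes, by = "division") |>
    dplyr::arrange(.data$division)
}
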