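#' Simulation parameters for synthetic clonal assays
#'
#' Builds the parameter object consumed by [simulate_clone_table()],
#' [simulate_granddaughter_families()] and [simulate_dosage_tables()].
#' Defaults reproduce the shape of a large cord-blood clonal screen:
#' ~5,600 wells seeded across nine CD34+ progenitor subsets from 17
#' donors, roughly 40% of them productive, clone yields spread over
#' orders of magnitude, per-clone lineage bias drawn from subset-specific
#' archetype mixtures, biased clones out-yielding equipotent ones, and
#' granddaughter quartets inheriting their ancestor's bias with high
#' probability.
#'
#' The generative model for one productive clone is: archetype (one of
#' the six lineage-bias archetypes or an equipotent archetype) drawn from
#' the subset's mixture; a six-part composition drawn from a Dirichlet
#' whose concentration is peaked on the archetype lineage (peak
#' `dominance`, off-target `off_alpha / bias_concentration`); total yield
#' drawn log10-normally with mean shifted upward by
#' `bias_yield_coupling * (1 - bias ratio)` so that strongly biased
#' compositions proliferate more; counts allocated multinomially.
#'
#' @param n_clones named integer vector of seeded wells per subset.
#' @param n_donors number of donors, assigned uniformly at random.
#' @param unproductive_fraction named numeric vector in `[0,1]` per subset;
#'   unproductive clones emit all-zero yield vectors.
#' @param archetype_mixture subsets x 7 matrix of weights over the
#'   archetypes `G, M, L, DC1, DC2, pDC, EQ`; rows are renormalized.
#' @param bias_concentration positive scalar; larger values concentrate
#'   compositions on the archetype lineage (lower bias ratios).
#' @param archetype_alpha optional 7 x 6 matrix (rows `G ... pDC, EQ`,
#'   columns the six lineages) of explicit Dirichlet concentrations per
#'   archetype, overriding the peaked default; lets specific off-target
#'   lineages co-occur with a bias (e.g. monocyte output alongside a
#'   granulocyte bias), which induces lineage co-ancestry.
#' @param dominance,off_alpha,equi_alpha Dirichlet concentration for the
#'   dominant lineage, the off-target lineages (divided by
#'   `bias_concentration`), and the symmetric equipotent archetype.
#' @param yield_log10_mean named numeric vector of log10 total-yield means
#'   per archetype.
#' @param yield_log10_sd positive scalar log10 yield spread.
#' @param bias_yield_coupling non-negative shift on log10 yield per unit
#'   of (1 - bias ratio).
#' @param inheritance_probability probability a granddaughter keeps its
#'   ancestor's archetype.
#' @param switch_matrix optional 6x6 row-stochastic matrix of switch
#'   destinations (rows = ancestor lineage, zero diagonal); default is a
#'   uniform kernel over the five other lineages.
#' @param switch_yield_penalty log10-yield handicap of bias-switched
#'   granddaughters.
#' @param inheritance_amplification multiplier on `dominance` for
#'   bias-inheriting granddaughters (inherited bias is amplified).
#' @param division_fraction fraction of HSC/MPP clones carrying a CFSE
#'   division label.
#' @param division_levels divisions sampled for labelled clones.
#' @param division_yield_decay log10-yield loss per recorded division.
#' @param culture culture-system label stamped on simulated clones.
#' @param seed integer seed; all draws are reproducible given it, and
#'   family/dosage simulations use fixed substreams so that changing the
#'   number of clones does not perturb them.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_clones = c(HSC = 360, MPP = 408, LMPP = 791,
                                    MLP = 720, BNKP = 542, CMP = 800,
                                    GMDP = 890, MDP = 357, CDP = 691),
                       n_donors = 17,
                       unproductive_fraction = c(HSC = 0.52, MPP = 0.52,
                                                 LMPP = 0.60, MLP = 0.60,
                                                 BNKP = 0.60, CMP = 0.60,
                                                 GMDP = 0.60, MDP = 0.60,
                                                 CDP = 0.60),
                       archetype_mixture = default_archetype_mixture(),
                       bias_concentration = 1,
                       archetype_alpha = NULL,
                       dominance = 4,
                       off_alpha = 0.8,
                       equi_alpha = 5,
                       yield_log10_mean = c(G = 2.4, M = 2.4, L = 2.4,
                                            DC1 = 2.4, DC2 = 2.4, pDC = 2.4,
                                            EQ = 3.3),
                       yield_log10_sd = 1,
                       bias_yield_coupling = 0.5,
                       inheritance_probability = 0.796,
                       switch_matrix = NULL,
                       switch_yield_penalty = 0.5,
                       inheritance_amplification = 2,
                       division_fraction = 0.2,
                       division_levels = c(0L, 3L, 6L),
                       division_yield_decay = 0.15,
                       culture = "MPFSG",
                       seed = 1L) {
  subs <- names(n_clones)
  if (is.null(subs) || !all(subs %in% subset_names())) {
    abort("`n_clones` must be named by progenitor subset.")
  }
  stopifnot(all(n_clones >= 0),
            n_donors >= 1,
            all(unproductive_fraction >= 0 & unproductive_fraction <= 1),
            bias_concentration > 0, dominance > 0, off_alpha > 0,
            equi_alpha > 0, yield_log10_sd > 0, bias_yield_coupling >= 0,
            inheritance_probability >= 0, inheritance_probability <= 1,
            switch_yield_penalty >= 0, inheritance_amplification > 0,
            division_fraction >= 0, division_fraction <= 1,
            division_yield_decay >= 0)
  if (!all(subs %in% names(unproductive_fraction))) {
    abort("`unproductive_fraction` must cover every subset in `n_clones`.")
  }
  archetypes <- c(lineage_names(), "EQ")
  if (!all(subs %in% rownames(archetype_mixture)) ||
      !identical(colnames(archetype_mixture), archetypes)) {
    abort("`archetype_mixture` must have subset rows and columns G, M, L, DC1, DC2, pDC, EQ.")
  }
  if (any(archetype_mixture < 0) || any(rowSums(archetype_mixture) <= 0)) {
    abort("`archetype_mixture` weights must be non-negative with positive row sums.")
  }
  archetype_mixture <- archetype_mixture / rowSums(archetype_mixture)
  if (!is.null(archetype_alpha)) {
    stopifnot(is.matrix(archetype_alpha),
              all(dim(archetype_alpha) == c(7, 6)),
              all(archetype_alpha > 0))
    dimnames(archetype_alpha) <- list(archetypes, lineage_names())
  }
  if (!is.null(switch_matrix)) {
    stopifnot(is.matrix(switch_matrix),
              all(dim(switch_matrix) == c(6, 6)),
              all(switch_matrix >= 0),
              all(abs(diag(switch_matrix)) == 0))
    switch_matrix <- switch_matrix / rowSums(switch_matrix)
    dimnames(switch_matrix) <- list(lineage_names(), lineage_names())
  }
  stopifnot(all(archetypes %in% names(yield_log10_mean)))
  culture <- match.arg(culture, culture_names())
  structure(list(
    n_clones = n_clones, n_donors = as.integer(n_donors),
    unproductive_fraction = unproductive_fraction,
    archetype_mixture = archetype_mixture,
    archetype_alpha = archetype_alpha,
    bias_concentration = bias_concentration, dominance = dominance,
    off_alpha = off_alpha, equi_alpha = equi_alpha,
    yield_log10_mean = yield_log10_mean, yield_log10_sd = yield_log10_sd,
    bias_yield_coupling = bias_yield_coupling,
    inheritance_probability = inheritance_probability,
    switch_matrix = switch_matrix,
    switch_yield_penalty = switch_yield_penalty,
    inheritance_amplification = inheritance_amplification,
    division_fraction = division_fraction,
    division_levels = as.integer(division_levels),
    division_yield_decay = division_yield_decay,
    culture = culture, seed = as.integer(seed)
  ), class = "sim_params")
}

#' @rdname sim_params
#' @export
default_archetype_mixture <- function() {
  m <- rbind(
    HSC  = c(0.17, 0.15, 0.14, 0.08, 0.10, 0.09, 0.27),
    MPP  = c(0.18, 0.16, 0.14, 0.08, 0.10, 0.09, 0.25),
    LMPP = c(0.10, 0.08, 0.35, 0.15, 0.07, 0.20, 0.05),
    MLP  = c(0.05, 0.05, 0.45, 0.12, 0.05, 0.23, 0.05),
    BNKP = c(0.02, 0.03, 0.70, 0.05, 0.03, 0.15, 0.02),
    CMP  = c(0.40, 0.30, 0.02, 0.05, 0.12, 0.04, 0.07),
    GMDP = c(0.35, 0.30, 0.02, 0.10, 0.15, 0.05, 0.03),
    MDP  = c(0.05, 0.40, 0.03, 0.15, 0.25, 0.10, 0.02),
    CDP  = c(0.03, 0.05, 0.01, 0.25, 0.35, 0.30, 0.01)
  )
  colnames(m) <- c(lineage_names(), "EQ")
  m / rowSums(m)
}

# Dirichlet draw, one composition per row of alpha
rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

archetype_alpha <- function(arch, params, amplify = 1) {
  lin <- lineage_names()
  if (!is.null(params$archetype_alpha)) {
    a <- params$archetype_alpha[arch, ]
    if (arch != "EQ") a[arch] <- a[arch] * amplify
    return(a)
  }
  if (arch == "EQ") return(setNames(rep(params$equi_alpha, 6), lin))
  a <- setNames(rep(params$off_alpha / params$bias_concentration, 6), lin)
  a[arch] <- params$dominance * amplify
  a
}

# composition + total for one productive clone
draw_clone_yield <- function(arch, params, amplify = 1, log10_shift = 0) {
  comp <- rdirichlet_one(archetype_alpha(arch, params, amplify))
  srt <- sort(comp, decreasing = TRUE)
  bias_ratio <- srt[2] / srt[1]
  mu <- params$yield_log10_mean[[arch]] +
    params$bias_yield_coupling * (1 - bias_ratio) + log10_shift
  total <- max(1, round(10^rnorm(1, mu, params$yield_log10_sd)))
  counts <- as.integer(rmultinom(1, total, comp))
  names(counts) <- lineage_names()
  counts
}

#' Simulate a clone table
#'
#' Draws a full clone table under `params` (see [sim_params()] for the
#' generative model). Unproductive clones emit all-zero yield vectors.
#' The per-clone generating archetype is recorded in the `truth`
#' attribute for parameter-recovery tests.
#'
#' @param params a [sim_params()] object.
#' @return A validated `clone_table` tibble with attributes `truth`
#'   (tibble: clone_id, archetype) and `params`.
#' @export
simulate_clone_table <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (sum(params$n_clones) == 0) abort("Zero clones requested.")
  withr::local_seed(params$seed)
  archetypes <- c(lineage_names(), "EQ")
  rows <- list(); truths <- list()
  for (sub in names(params$n_clones)) {
    n <- params$n_clones[[sub]]
    if (n == 0) next
    unprod <- runif(n) < params$unproductive_fraction[[sub]]
    arch <- sample(archetypes, n, replace = TRUE,
                   prob = params$archetype_mixture[sub, ])
    arch[unprod] <- NA_character_
    donor <- sprintf("D%02d", sample.int(params$n_donors, n, replace = TRUE))
    division <- rep(NA_integer_, n)
    if (sub %in% c("HSC", "MPP") && params$division_fraction > 0) {
      tracked <- runif(n) < params$division_fraction
      division[tracked] <- params$division_levels[
        sample.int(length(params$division_levels), sum(tracked),
                   replace = TRUE)]
    }
    counts <- matrix(0L, n, 6, dimnames = list(NULL, lineage_names()))
    for (i in which(!unprod)) {
      shift <- if (!is.na(division[i])) {
        -params$division_yield_decay * division[i]
      } else 0
      counts[i, ] <- draw_clone_yield(arch[i], params, log10_shift = shift)
    }
    rows[[sub]] <- tibble(
      clone_id = sprintf("%s_%04d", sub, seq_len(n)),
      donor_id = donor, subset = sub, culture = params$culture,
      division = division
    ) |> dplyr::bind_cols(as_tibble(counts))
    truths[[sub]] <- tibble(clone_id = rows[[sub]]$clone_id, archetype = arch)
  }
  out <- validate_clone_table(dplyr::bind_rows(rows))
  attr(out, "truth") <- dplyr::bind_rows(truths)
  attr(out, "params") <- params
  out
}

#' Simulate granddaughter families
#'
#' Each traced ancestor contributes 2-4 individually cultured
#' granddaughters. A granddaughter keeps the ancestor's bias archetype
#' with probability `inheritance_probability` (its composition drawn with
#' amplified dominance, emulating bias reinforcement over division);
#' otherwise it switches to a different lineage drawn from the switch
#' kernel and pays a log10-yield penalty (bias-switched progeny are less
#' proliferative).
#'
#' Draws come from a substream independent of [simulate_clone_table()]
#' under the same seed.
#'
#' @param params a [sim_params()] object.
#' @param n_families number of traced ancestors (>= 1).
#' @param subset progenitor subset of the ancestors.
#' @return Long tibble: `family_id`, `subset`, `well_id`, `G ... pDC`,
#'   with a `truth` attribute (ancestor archetype, granddaughter
#'   archetype, inherited flag).
#' @export
simulate_granddaughter_families <- function(params, n_families,
                                            subset = "HSC") {
  stopifnot(inherits(params, "sim_params"), n_families >= 1)
  subset <- match.arg(subset, subset_names())
  withr::local_seed(params$seed + 1000003L)
  lin <- lineage_names()
  mix <- params$archetype_mixture[subset, lin]  # biased archetypes only
  mix <- mix / sum(mix)
  switch_kernel <- params$switch_matrix
  if (is.null(switch_kernel)) {
    switch_kernel <- matrix(1 / 5, 6, 6, dimnames = list(lin, lin))
    diag(switch_kernel) <- 0
  }
  fams <- list(); truths <- list()
  for (f in seq_len(n_families)) {
    anc <- sample(lin, 1, prob = mix)
    n_gd <- sample(2:4, 1)
    gd_arch <- character(n_gd); inherited <- logical(n_gd)
    counts <- matrix(0L, n_gd, 6, dimnames = list(NULL, lin))
    for (g in seq_len(n_gd)) {
      inherited[g] <- runif(1) < params$inheritance_probability
      if (inherited[g]) {
        gd_arch[g] <- anc
        counts[g, ] <- draw_clone_yield(
          anc, params, amplify = params$inheritance_amplification)
      } else {
        gd_arch[g] <- sample(lin, 1, prob = switch_kernel[anc, ])
        counts[g, ] <- draw_clone_yield(
          gd_arch[g], params, log10_shift = -params$switch_yield_penalty)
      }
    }
    fid <- sprintf("F%04d", f)
    fams[[f]] <- tibble(family_id = fid, subset = subset,
                        well_id = sprintf("%s_w%d", fid, seq_len(n_gd))) |>
      dplyr::bind_cols(as_tibble(counts))
    truths[[f]] <- tibble(family_id = fid,
                          well_id = fams[[f]]$well_id,
                          ancestor_archetype = anc,
                          granddaughter_archetype = gd_arch,
                          inherited = inherited)
  }
  out <- dplyr::bind_rows(fams)
  attr(out, "truth") <- dplyr::bind_rows(truths)
  attr(out, "params") <- params
  class(out) <- unique(c("granddaughter_families", class(out)))
  out
}

#' Simulate TF-dosage and lineage-bias composition tables
#'
#' Produces the per-subset percentage tables correlated by
#' [correlate_compositions()]: the lineage-bias composition (share of
#' productive clones biased to each lineage, from the archetype mixture)
#' and six transcription-factor gate occupancies generated as noisy
#' images of the bias composition under a known gate-to-lineage
#' correspondence. Both tables' rows sum to 100.
#'
#' @param params a [sim_params()] object.
#' @param noise_sd standard deviation (percentage points) of the Gaussian
#'   noise added to gate percentages before renormalization.
#' @param correspondence named character vector mapping gate names to
#'   lineage names; default pairs each gate with its canonical lineage
#'   (IRF8-/PU.1lo with G, IRF8lo-int/PU.1hi with M, IRF8int/PU.1lo with
#'   L, IRF8hi/PU.1hi with DC1, IRF8int/PU.1hi with DC2, IRF8hi/PU.1lo
#'   with pDC).
#' @return A `dosage_tables` list: `gates`, `bias` (tibbles keyed by
#'   `subset`), `correspondence`, `noise_sd`.
#' @export
simulate_dosage_tables <- function(params, noise_sd = 3,
                                   correspondence = NULL) {
  stopifnot(inherits(params, "sim_params"), noise_sd >= 0)
  withr::local_seed(params$seed + 2000003L)
  lin <- lineage_names()
  gates <- dosage_gate_names()
  if (is.null(correspondence)) correspondence <- setNames(lin, gates)
  stopifnot(identical(sort(names(correspondence)), sort(gates)),
            all(correspondence %in% lin))
  subs <- rownames(params$archetype_mixture)
  bias <- params$archetype_mixture[, lin, drop = FALSE]
  bias <- 100 * bias / rowSums(bias)
  gm <- sapply(gates, function(g) bias[, correspondence[[g]]])
  rownames(gm) <- subs
  if (noise_sd > 0) {
    gm <- gm + matrix(rnorm(length(gm), 0, noise_sd), nrow(gm))
    gm[gm < 0] <- 0
    gm <- 100 * gm / rowSums(gm)
  }
  structure(list(
    gates = dplyr::bind_cols(tibble(subset = subs), as_tibble(gm)),
    bias = dplyr::bind_cols(tibble(subset = subs), as_tibble(bias)),
    correspondence = correspondence,
    noise_sd = noise_sd
  ), class = "dosage_tables")
}

#' @rdname simulate_dosage_tables
#' @export
dosage_gate_names <- function() {
  c("IRF8neg_PU1lo", "IRF8loint_PU1hi", "IRF8int_PU1lo",
    "IRF8hi_PU1hi", "IRF8int_PU1hi", "IRF8hi_PU1lo")
}
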