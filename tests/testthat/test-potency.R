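clone_row <- function(yields, subset = "HSC", id = "x1") {
  tibble::tibble(clone_id = id, donor_id = "D01", subset = subset,
                 culture = "MPFSG",
                 G = yields[1], M = yields[2], L = yields[3],
                 DC1 = yields[4], DC2 = yields[5], pDC = yields[6])
}

test_that("positivity thresholds follow the 7 / 2-for-CDP rule", {
  th <- positivity_thresholds()
  expect_true(all(th[setdiff(subset_names(), "CDP")] == 7))
  expect_identical(unname(th["CDP"]), 2L)

  pos <- call_positivity(clone_row(c(6L, 0L, 0L, 0L, 0L, 0L)))
  expect_false(pos$productive)
  pos7 <- call_positivity(clone_row(c(7L, 0L, 0L, 0L, 0L, 0L)))
  expect_true(pos7$productive)
  cdp <- call_positivity(clone_row(c(2L, 0L, 0L, 0L, 0L, 0L), subset = "CDP"))
  expect_true(cdp$productive)
  expect_true(cdp$pos_G)
  expect_false(call_positivity(
    clone_row(c(0L, 0L, 0L, 0L, 0L, 0L)))$productive)
})

test_that("bias profile arithmetic matches the ratio definitions", {
  p <- bias_profiles(clone_row(c(100L, 50L, 0L, 0L, 0L, 0L)))
  expect_equal(p$equipotency_ratio, 0.5)
  expect_equal(p$bias_ratio, 0.5)
  expect_equal(p$cd_G, 2 / 3)
  expect_equal(p$cd_M, 1 / 3)
  expect_identical(p$predominant, "G")

  eq <- bias_profiles(clone_row(rep(40L, 6)))
  expect_equal(eq$equipotency_ratio, 1)
  expect_equal(eq$bias_ratio, 1)

  uni <- bias_profiles(clone_row(c(500L, 0L, 0L, 0L, 0L, 0L)))
  expect_true(is.na(uni$equipotency_ratio))
  expect_true(is.na(uni$bias_ratio))
  expect_equal(uni$cd_G, 1)
  expect_equal(unname(uni$n_lineages), 1)

  unprod <- clone_row(c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_error(bias_profiles(unprod), "productive",
               class = "clone_validation_error")
})

test_that("commitment degrees sum to one and ratios live in (0, 1]", {
  tb <- simulate_clone_table(small_params(n_clones = c(HSC = 300),
                                          unproductive_fraction = c(HSC = 0.3)))
  prof <- bias_profiles(tb)
  cd <- as.matrix(prof[, paste0("cd_", lineage_names())])
  expect_true(all(abs(rowSums(cd) - 1) <= 1e-12))
  nu <- dplyr::filter(prof, n_lineages >= 2)
  expect_true(all(nu$equipotency_ratio > 0 & nu$equipotency_ratio <= 1))
  expect_true(all(nu$bias_ratio > 0 & nu$bias_ratio <= 1))
  # with exactly two positive lineages the two ratios coincide
  two <- dplyr::filter(nu, n_lineages == 2)
  expect_gt(nrow(two), 0)
  expect_equal(two$bias_ratio, two$equipotency_ratio)
})

test_that("profiles are invariant under per-clone rescaling", {
  tb <- validate_clone_table(tiny_clone_table())
  scaled <- tb
  for (col in lineage_names()) scaled[[col]] <- scaled[[col]] * 3L
  a <- bias_profiles(tb)
  b <- bias_profiles(scaled)
  ratio_cols <- c(paste0("cd_", lineage_names()),
                  "equipotency_ratio", "bias_ratio", "predominant")
  expect_equal(a[ratio_cols], b[ratio_cols])
})

test_that("equipotency over positive lineages differs from over all six", {
  row <- clone_row(c(100L, 10L, 0L, 0L, 0L, 0L))
  over_pos <- bias_profiles(row)$equipotency_ratio
  over_all <- bias_profiles(row, equipotency_over = "all")$equipotency_ratio
  expect_equal(over_pos, 0.1)
  expect_equal(over_all, 0)
})

test_that("ties in predominant lineage break by canonical order", {
  expect_message(
    p <- bias_profiles(clone_row(c(50L, 50L, 0L, 0L, 0L, 0L))),
    "tied")
  expect_identical(p$predominant, "G")
  expect_true(p$tie)
})

test_that("potency composition reports efficiency and SE by the formula", {
  tb <- dplyr::bind_rows(lapply(1:100, function(i) {
    clone_row(if (i <= 50) c(20L, 0L, 0L, 0L, 0L, 0L) else rep(0L, 6),
              id = sprintf("h%03d", i))
  }))
  comp <- potency_composition(tb)
  expect_equal(comp$efficiency$efficiency, 0.5)
  expect_equal(comp$efficiency$se, sqrt(0.25 / 100))
  g <- dplyr::filter(comp$composition, lineage == "G")
  expect_equal(g$percent, 100)
  expect_equal(sum(comp$composition$percent), 100)
})

test_that("bias-yield association summarizes histograms and cumulative shares", {
  tb <- dplyr::bind_rows(lapply(1:10, function(i) {
    clone_row(c(100L + i, 10L + i, 0L, 0L, 0L, 0L), id = sprintf("c%d", i))
  }))
  assoc <- bias_yield_association(bias_profiles(tb))
  cum <- dplyr::filter(assoc$cumulative, statistic == "equipotency_ratio")
  expect_equal(cum$pct_below_0.5, 100)
  expect_equal(cum$pct_above_0.5, 0)
  expect_equal(sum(dplyr::filter(assoc$histograms,
                                 statistic == "bias_ratio")$fraction), 1)
})

test_that("degenerate yields flag the Spearman correlation", {
  tb <- dplyr::bind_rows(lapply(1:5, function(i) {
    clone_row(c(60L, 40L, 0L, 0L, 0L, 0L), id = sprintf("d%d", i))
  }))
  assoc <- bias_yield_association(bias_profiles(tb))
  expect_true(all(assoc$spearman$degenerate))
  expect_true(all(is.na(assoc$spearman$rho)))

  one <- bias_profiles(clone_row(c(30L, 20L, 0L, 0L, 0L, 0L)))
  expect_error(bias_yield_association(one), "at least 3")
})

test_that("biased clones out-yield equipotent ones in the generator", {
  mix <- default_archetype_mixture()
  mix["HSC", ] <- c(rep(1 / 6, 6), 0)  # isolate the bias-yield coupling
  tb <- simulate_clone_table(small_params(n_clones = c(HSC = 1000),
                                          unproductive_fraction = c(HSC = 0),
                                          archetype_mixture = mix,
                                          bias_yield_coupling = 1))
  assoc <- bias_yield_association(bias_profiles(tb))
  rho <- dplyr::filter(assoc$spearman,
                       statistic == "equipotency_ratio")$rho
  expect_lt(rho, 0)
})
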