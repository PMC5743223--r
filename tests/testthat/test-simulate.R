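test_that("the generator is deterministic given a seed", {
  p <- small_params()
  t1 <- simulate_clone_table(p)
  t2 <- simulate_clone_table(p)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "truth"), attr(t2, "truth"))
  t3 <- simulate_clone_table(small_params(seed = 43))
  expect_false(identical(clone_matrix(t1), clone_matrix(t3)))
})

test_that("degenerate unproductive fractions behave as limits", {
  allzero <- simulate_clone_table(small_params(
    unproductive_fraction = c(HSC = 1, CMP = 1, MDP = 1)))
  expect_true(all(clone_matrix(allzero) == 0))
  allprod <- simulate_clone_table(small_params(
    unproductive_fraction = c(HSC = 0, CMP = 0, MDP = 0)))
  expect_true(all(rowSums(clone_matrix(allprod)) > 0))
})

test_that("observed unproductive share matches the requested rate", {
  n <- 2000
  tb <- simulate_clone_table(small_params(
    n_clones = c(HSC = n), unproductive_fraction = c(HSC = 0.5),
    division_fraction = 0))
  share <- mean(rowSums(clone_matrix(tb)) == 0)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("clonal yields are heavy-tailed across orders of magnitude", {
  tb <- simulate_clone_table(small_params(n_clones = c(HSC = 800),
                                          unproductive_fraction = c(HSC = 0)))
  tot <- rowSums(clone_matrix(tb))
  expect_gt(log10(quantile(tot, 0.95) / quantile(tot, 0.05)), 2)
})

test_that("raising bias_concentration lowers the median bias ratio", {
  med_bias <- function(bc) {
    tb <- simulate_clone_table(small_params(
      n_clones = c(CMP = 600), unproductive_fraction = c(CMP = 0),
      bias_concentration = bc))
    median(bias_profiles(tb)$bias_ratio, na.rm = TRUE)
  }
  m <- vapply(c(0.25, 1, 4), med_bias, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("a dominant-G archetype is recovered as the dominant bias group", {
  mix <- default_archetype_mixture()
  mix["CMP", ] <- c(0.85, 0.03, 0.03, 0.03, 0.03, 0.03, 0)
  tb <- simulate_clone_table(small_params(
    n_clones = c(CMP = 400), unproductive_fraction = c(CMP = 0.2),
    archetype_mixture = mix, bias_concentration = 6))
  comp <- potency_composition(tb)$composition
  g_row <- dplyr::filter(comp, subset == "CMP", lineage == "G")
  expect_identical(
    dplyr::slice_max(dplyr::filter(comp, subset == "CMP"),
                     proportion, n = 1)$lineage, "G")
  expect_lt(abs(g_row$proportion - 0.85), 3 * sqrt(0.85 * 0.15 / g_row$n))
})

test_that("granddaughter inheritance hits its degenerate limits", {
  # near-deterministic compositions so realized bias equals the archetype
  fams1 <- simulate_granddaughter_families(
    small_params(inheritance_probability = 1, bias_concentration = 40), 60)
  expect_true(all(attr(fams1, "truth")$inherited))
  calls1 <- classify_inheritance(fams1)
  expect_equal(inheritance_rate(calls1)$rate, 1)

  fams0 <- simulate_granddaughter_families(
    small_params(inheritance_probability = 0, bias_concentration = 8), 60)
  truth0 <- attr(fams0, "truth")
  expect_true(all(!truth0$inherited))
})

test_that("family sizes are 2-4 and family draws ignore the clone stream", {
  p1 <- small_params()
  p2 <- small_params(n_clones = c(HSC = 5))
  f1 <- simulate_granddaughter_families(p1, 40)
  f2 <- simulate_granddaughter_families(p2, 40)
  expect_equal(as.data.frame(f1), as.data.frame(f2), ignore_attr = TRUE)
  sizes <- table(f1$family_id)
  expect_true(all(sizes >= 2 & sizes <= 4))
})

test_that("dosage tables are proper percentage tables with known truth", {
  p <- small_params()
  noiseless <- simulate_dosage_tables(p, noise_sd = 0)
  gm <- as.matrix(noiseless$gates[, -1])
  bm <- as.matrix(noiseless$bias[, -1])
  expect_equal(unname(rowSums(gm)), rep(100, nrow(gm)))
  expect_equal(unname(rowSums(bm)), rep(100, nrow(bm)))
  r <- correlate_compositions(noiseless)$r
  matched <- diag(r[dosage_gate_names(), lineage_names()])
  expect_equal(unname(matched), rep(1, 6), tolerance = 1e-12)

  noisy <- simulate_dosage_tables(p, noise_sd = 4)
  expect_equal(unname(rowSums(as.matrix(noisy$gates[, -1]))),
               rep(100, nrow(gm)))
})

test_that("shuffling the gate-lineage correspondence destroys matched r", {
  p <- small_params()
  shuffle <- setNames(lineage_names()[c(3, 4, 5, 6, 1, 2)],
                      dosage_gate_names())
  dt <- simulate_dosage_tables(p, noise_sd = 1, correspondence = shuffle)
  r <- correlate_compositions(dt)$r
  matched <- diag(r[dosage_gate_names(), lineage_names()])
  expect_lt(mean(matched), 0.3)
})

test_that("invalid parameters are rejected", {
  expect_error(sim_params(n_clones = c(1, 2)), "named")
  expect_error(sim_params(unproductive_fraction = c(HSC = 1.2)))
  expect_error(sim_params(bias_concentration = 0))
  expect_error(simulate_clone_table(sim_params(n_clones = c(HSC = 0))),
               "Zero clones")
})
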