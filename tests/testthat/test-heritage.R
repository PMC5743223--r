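gd_family <- function(yields, fid = "F1") {
  n <- nrow(yields)
  tibble::tibble(family_id = fid, subset = "HSC",
                 well_id = sprintf("%s_w%d", fid, seq_len(n)),
                 G = yields[, 1], M = yields[, 2], L = yields[, 3],
                 DC1 = yields[, 4], DC2 = yields[, 5], pDC = yields[, 6])
}

test_that("ancestor potency is the granddaughter sum, order-invariant", {
  fam <- gd_family(rbind(c(10L, 0L, 0L, 0L, 0L, 0L),
                         c(0L, 5L, 0L, 0L, 0L, 0L)))
  anc <- infer_ancestor_potency(fam)
  expect_identical(unname(anc), c(10, 5, 0, 0, 0, 0))
  expect_identical(anc, infer_ancestor_potency(fam[2:1, ]))
  expect_error(infer_ancestor_potency(fam[1, ]),
               class = "family_exclusion_error")
})

test_that("granddaughters are classified against the ancestor-sum bias", {
  fam <- gd_family(rbind(c(100L, 10L, 0L, 0L, 0L, 0L),
                         c(80L, 20L, 0L, 0L, 0L, 0L),
                         c(10L, 90L, 0L, 0L, 0L, 0L)))
  calls <- classify_inheritance(fam)
  expect_identical(calls$ancestor_bias, rep("G", 3))
  expect_identical(calls$inherited, c(TRUE, TRUE, FALSE))
  expect_identical(calls$predominant, c("G", "G", "M"))
  # conservation
  r <- inheritance_rate(calls)
  expect_identical(r$inherited + r$switched, r$n)
  expect_identical(r$n, nrow(calls))
})

test_that("unproductive granddaughters are dropped; thin families excluded", {
  fam <- gd_family(rbind(c(100L, 10L, 0L, 0L, 0L, 0L),
                         c(3L, 2L, 0L, 0L, 0L, 0L),   # below threshold 7
                         c(40L, 10L, 0L, 0L, 0L, 0L)))
  expect_warning(calls <- classify_inheritance(fam), "unproductive")
  expect_identical(nrow(calls), 2L)

  thin <- dplyr::bind_rows(
    gd_family(rbind(c(100L, 0L, 0L, 0L, 0L, 0L),
                    c(1L, 0L, 0L, 0L, 0L, 0L)), fid = "F1"),
    gd_family(rbind(c(50L, 10L, 0L, 0L, 0L, 0L),
                    c(40L, 20L, 0L, 0L, 0L, 0L)), fid = "F2"))
  warns <- capture_warnings(calls2 <- classify_inheritance(thin))
  expect_match(warns, "excluded", all = FALSE)
  expect_identical(unique(calls2$family_id), "F2")
})

test_that("the switch matrix tallies directions with conserved rows", {
  fam1 <- gd_family(rbind(c(100L, 10L, 0L, 0L, 0L, 0L),
                          c(90L, 10L, 0L, 0L, 0L, 0L)), "F1")
  fam2 <- gd_family(rbind(c(100L, 30L, 0L, 0L, 0L, 0L),
                          c(10L, 80L, 0L, 0L, 0L, 0L)), "F2")
  calls <- classify_inheritance(dplyr::bind_rows(fam1, fam2))
  m <- switch_direction_matrix(calls)
  expect_identical(m["G", "M"], 1L)
  expect_identical(m["G", "G"], 3L)
  expect_identical(sum(m), nrow(calls))
  expect_equal(unname(rowSums(m)["G"]), 4)
  all_inh <- classify_inheritance(fam1)
  m1 <- switch_direction_matrix(all_inh)
  expect_true(all(m1[upper.tri(m1) | lower.tri(m1)] == 0))
})

test_that("commitment fold-change is the ratio of own-lineage commitments", {
  anc <- c(G = 45L, M = 55L, L = 0L, DC1 = 0L, DC2 = 0L, pDC = 0L)
  gd <- c(G = 90L, M = 10L, L = 0L, DC1 = 0L, DC2 = 0L, pDC = 0L)
  expect_equal(commitment_fold_change(anc, gd), 0.9 / 0.45)
  expect_equal(commitment_fold_change(anc, anc), 1)
  gd_new <- c(G = 0L, M = 0L, L = 20L, DC1 = 0L, DC2 = 0L, pDC = 0L)
  expect_warning(fc <- commitment_fold_change(anc, gd_new), "commitment")
  expect_true(is.na(fc))
  expect_error(commitment_fold_change(anc, rep(0L, 6)), "productive")
})

test_that("inherited progeny amplify their bias beyond the family pool", {
  p <- small_params(inheritance_probability = 0.7,
                    inheritance_amplification = 3, bias_concentration = 2)
  fams <- simulate_granddaughter_families(p, 250)
  calls <- suppressWarnings(classify_inheritance(fams))
  inh <- dplyr::filter(calls, .data$inherited, .data$fold_change_defined)
  expect_gt(mean(inh$fold_change), 1)
  # inherited progeny end up more committed to their lineage than
  # switched siblings (whose fold-change denominator is the ancestor's
  # near-zero commitment to the new lineage and is thus not comparable)
  sw <- dplyr::filter(calls, !.data$inherited)
  expect_gt(mean(inh$commitment), mean(sw$commitment))
})

test_that("inheritance-rate recovery is within binomial error at p = 0.8", {
  p <- small_params(inheritance_probability = 0.8, bias_concentration = 6)
  fams <- simulate_granddaughter_families(p, 500)
  calls <- suppressWarnings(classify_inheritance(fams))
  truth <- attr(fams, "truth")
  r <- inheritance_rate(calls)
  se <- sqrt(0.8 * 0.2 / r$n)
  expect_lt(abs(r$rate - 0.8), 3 * se + 0.02)  # small archetype-call noise
  # against the generator's own labels the match is near-perfect
  merged <- dplyr::left_join(calls, truth, by = c("family_id", "well_id"))
  expect_gt(mean(merged$inherited.x == merged$inherited.y), 0.9)
})

test_that("the estimator is unbiased over repeated simulations", {
  ests <- vapply(1:200, function(s) {
    p <- small_params(inheritance_probability = 0.8,
                      bias_concentration = 8, seed = 5000 + s)
    fams <- simulate_granddaughter_families(p, 60)
    calls <- suppressWarnings(classify_inheritance(fams))
    inheritance_rate(calls)$rate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.8), 0.01)
})

test_that("sibling yield comparison pairs classes within families", {
  p <- small_params(inheritance_probability = 0.6, switch_yield_penalty = 1,
                    bias_concentration = 6)
  fams <- simulate_granddaughter_families(p, 200)
  calls <- suppressWarnings(classify_inheritance(fams))
  pairs <- sibling_yield_comparison(calls)
  expect_gt(nrow(pairs), 20)
  expect_gt(median(log10(pairs$mean_inherited / pairs$mean_switched)), 0)
})
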