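make_two_donor_table <- function(scale_b = 1L) {
  base <- tibble::tibble(
    clone_id = sprintf("a%d", 1:4), donor_id = "A", subset = "HSC",
    culture = "MPFSG",
    G = c(10L, 20L, 40L, 80L), M = c(5L, 10L, 20L, 40L),
    L = 0L, DC1 = 0L, DC2 = 0L, pDC = 0L)
  other <- base
  other$clone_id <- sprintf("b%d", 1:4)
  other$donor_id <- "B"
  for (col in c("G", "M")) other[[col]] <- other[[col]] * scale_b
  dplyr::bind_rows(base, other)
}

test_that("identical donors get unit factors; 10x donor gets 10x factor", {
  f1 <- donor_size_factors(make_two_donor_table(1L))
  expect_equal(f1$factor, c(1, 1))
  f10 <- donor_size_factors(make_two_donor_table(10L))
  ratio <- f10$factor[f10$donor_id == "B"] / f10$factor[f10$donor_id == "A"]
  expect_equal(ratio, 10)
  # factors are mean-one in the geometric sense
  expect_equal(exp(mean(log(f10$factor))), 1)
})

test_that("normalization equalizes per-donor geometric means and is idempotent", {
  tb <- simulate_clone_table(small_params(n_donors = 5))
  norm <- apply_donor_size_factors(tb)
  gm <- norm |>
    dplyr::mutate(total = G + M + L + DC1 + DC2 + pDC) |>
    dplyr::filter(total > 0) |>
    dplyr::group_by(subset, donor_id) |>
    dplyr::summarise(gmean = exp(mean(log(total))), .groups = "drop_last") |>
    dplyr::summarise(spread = diff(range(gmean)) / mean(gmean),
                     .groups = "drop")
  expect_true(all(gm$spread < 1e-9))

  # re-deriving factors from the normalized totals gives all ones
  renorm <- norm |>
    dplyr::mutate(dplyr::across(dplyr::all_of(lineage_names()),
                                ~as.integer(round(.x * 1e3))))
  f2 <- suppressWarnings(donor_size_factors(renorm))
  expect_equal(f2$factor[!f2$flagged],
               rep(1, sum(!f2$flagged)), tolerance = 1e-3)
})

test_that("bias statistics are invariant under donor size factors", {
  tb <- simulate_clone_table(small_params())
  before <- bias_profiles(tb)
  norm <- apply_donor_size_factors(tb)
  m <- clone_matrix(tb)
  mn <- as.matrix(as.data.frame(norm)[, lineage_names()])
  # per-clone ratios computed on scaled yields match the raw ones
  keep <- call_positivity(tb)$productive
  expect_equal(mn[keep, ] / rowSums(mn)[keep],
               m[keep, ] / rowSums(m)[keep], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(before$predominant,
                   lineage_names()[apply(mn[keep, ], 1, which.max)])
})

test_that("all-zero donor-subset groups are flagged and left unscaled", {
  tb <- tiny_clone_table()
  tb[3, lineage_names()] <- as.list(rep(0L, 6))
  expect_warning(f <- donor_size_factors(tb), "zero-yield")
  expect_true(f$flagged[f$subset == "CDP"])
  norm <- suppressWarnings(apply_donor_size_factors(tb))
  expect_equal(unlist(norm[3, lineage_names()]), unlist(tb[3, lineage_names()]),
               ignore_attr = TRUE)
})

test_that("lineage factors equalize column geometric means", {
  set.seed(9)
  m <- matrix(rpois(300, 40) + 1, 50, 6,
              dimnames = list(NULL, lineage_names()))
  res0 <- lineage_size_factors(m, pseudocount = 0)
  gms <- apply(res0$scaled, 2, function(x) exp(mean(log(x[x > 0]))))
  expect_lt(diff(range(gms)) / mean(gms), 1e-9)

  # already-equal columns give unit factors
  eq <- matrix(rep(c(2, 8), each = 6), 2, 6, byrow = TRUE,
               dimnames = list(NULL, lineage_names()))
  expect_equal(unname(lineage_size_factors(eq, pseudocount = 0)$factors),
               rep(1, 6))
})

test_that("lineage factors are exactly scale-equivariant without pseudocount", {
  set.seed(10)
  m <- matrix(rpois(120, 50) + 1, 20, 6,
              dimnames = list(NULL, lineage_names()))
  m[, "pDC"] <- m[, "G"] / 10
  f <- lineage_size_factors(m, pseudocount = 0)$factors
  expect_equal(unname(f["pDC"] / f["G"]), 0.1, tolerance = 1e-12)
  # with the default pseudocount the ratio is close but not exact
  f1 <- lineage_size_factors(m, pseudocount = 1)$factors
  expect_equal(unname(f1["pDC"] / f1["G"]), 0.1, tolerance = 0.1)
})

test_that("all-zero lineage columns are flagged", {
  m <- cbind(G = c(5, 9), M = c(0, 0), L = c(3, 4))
  expect_warning(res <- lineage_size_factors(m), "All-zero")
  expect_identical(res$flagged, "M")
  expect_true(is.na(res$factors["M"]))
  expect_identical(res$scaled[, "M"], c(0, 0))
})

test_that("log10 transform honours its contract", {
  expect_equal(log10_transform(matrix(0), 1), matrix(0))
  expect_equal(log10_transform(matrix(999), 1), matrix(3))
  expect_error(log10_transform(matrix(c(0, 5)), 0), "pseudocount")
  x <- matrix(c(3, 1, 4, 1, 5, 9), 2)
  expect_identical(order(log10_transform(x, 1)), order(x))
})
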