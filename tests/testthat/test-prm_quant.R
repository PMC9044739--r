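test_that("precursor roll-up sums the four most prominent transitions", {
  expect_equal(rollup_precursor(c(5, 3, 2, 1, 0.5)), 11)
  expect_equal(rollup_precursor(7), 7)
  expect_equal(rollup_precursor(c(NA, 4, NA, 6)), 10)
  expect_true(is.na(rollup_precursor(c(NA_real_, NA_real_))))
  expect_error(rollup_precursor(c(3, -1)), "non-negative")
})

test_that("roll-up equals the brute-force best-subset oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    areas <- round(runif(n, 0, 100), 2)
    oracle <- if (n <= 4) sum(areas)
    else max(combn(areas, 4, sum)) # top-4 sum == max over all 4-subsets
    expect_equal(rollup_precursor(areas), oracle)
  }
})

test_that("roll-up is permutation-invariant and scale-equivariant", {
  set.seed(1)
  areas <- runif(7, 0, 50)
  ids <- sprintf("y%d", 1:7)
  perm <- sample(7)
  expect_equal(rollup_precursor(areas[perm], ids[perm]),
               rollup_precursor(areas, ids))
  expect_equal(rollup_precursor(3 * areas, ids),
               3 * rollup_precursor(areas, ids))
})

test_that("ties at the fourth-largest area break deterministically", {
  areas <- c(10, 8, 6, 4, 4, 4)
  ids <- c("y9", "y8", "y7", "y6", "y5", "y4")
  # three-way tie at 4; exactly one joins the top four either way
  expect_equal(rollup_precursor(areas, ids), 28)
  expect_equal(rollup_precursor(rev(areas), rev(ids)), 28)
})

test_that("protein roll-up skips missing and never invents zeros", {
  expect_equal(rollup_protein(c(4, 6)), 10)
  expect_equal(rollup_protein(c(4, NA)), 4)
  expect_true(is.na(rollup_protein(c(NA_real_, NA_real_))))
  expect_equal(rollup_protein(rep(2.5, 4)), 10) # k equal precursors -> k*q
})

test_that("quantify_proteins builds the matrix and validates input", {
  sim <- tiny_cohort(seed = 3)
  qt <- quantify_proteins(sim$transitions)
  expect_s3_class(qt, "quant_table")
  expect_setequal(quant_samples(qt), sim$patients$sample_id)
  expect_true("A1AG_BOVIN" %in% quant_proteins(qt))
  expect_false("A1AG_BOVIN" %in% candidate_proteins(qt))
  expect_true(all(qt$mat >= 0, na.rm = TRUE))
  expect_true(all(qt$state[!is.na(qt$mat)] == "raw"))

  dup <- rbind(sim$transitions, sim$transitions[1, ])
  expect_error(quantify_proteins(dup), "duplicate")
  expect_error(quantify_proteins(sim$transitions[, -6]), "lacks column")
})

test_that("a renamed transition-report dialect is ingested via col_map", {
  sim <- tiny_cohort(seed = 3)
  renamed <- sim$transitions
  names(renamed) <- c("Replicate", "Protein", "Peptide", "Charge",
                      "FragmentIon", "Area")
  qt1 <- quantify_proteins(sim$transitions)
  qt2 <- quantify_proteins(renamed,
                           col_map = c(sample_id = "Replicate",
                                       protein = "Protein",
                                       peptide = "Peptide",
                                       precursor_charge = "Charge",
                                       transition_id = "FragmentIon",
                                       area = "Area"))
  expect_equal(qt1$mat, qt2$mat)
})

test_that("normalization divides by the per-sample reference", {
  mat <- matrix(c(10, 30, 2, 3), 2, 2,
                dimnames = list(c("s1", "s2"), c("P1", "REF")))
  qt <- prmstrat:::new_quant_table(mat, state = "raw",
                                   reference_proteins = "REF")
  norm <- normalize_to_reference(qt, "REF")
  expect_equal(unname(norm$mat[, "P1"]), c(5, 10))
  expect_equal(unname(norm$mat[, "REF"]), c(1, 1))
  expect_true(all(norm$state == "normalized"))
  # idempotent
  again <- normalize_to_reference(norm, "REF")
  expect_equal(again$mat, norm$mat)
})

test_that("a missing or zero normalizer halts and names the sample", {
  mat <- matrix(c(10, 30, 2, NA), 2, 2,
                dimnames = list(c("s1", "s2"), c("P1", "REF")))
  qt <- prmstrat:::new_quant_table(mat, state = "raw",
                                   reference_proteins = "REF")
  expect_error(normalize_to_reference(qt, "REF"), "s2")
})

test_that("normalization removes a noise-free batch factor exactly", {
  sim <- simulate_cohort(sim_config(n_patients = 8, n_proteins = 4,
                                    effect_log2 = 0, batch_sigma = 1,
                                    recurrence_rate = 0,
                                    noise_sigma = 0, mnar_prob = 0,
                                    mcar_prob = 0, seed = 12))
  expect_gt(diff(range(sim$truth$batch_factors)), 0.1)
  norm <- normalize_to_reference(quantify_proteins(sim$transitions))
  for (p in candidate_proteins(norm))
    expect_equal(diff(range(norm$mat[, p])), 0, tolerance = 1e-12)
})

test_that("quantity tables round-trip through delimited text", {
  sim <- tiny_cohort(seed = 3, mcar_prob = 0.2)
  qt <- normalize_to_reference(quantify_proteins(sim$transitions))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(qt, f)
  back <- read_quant_table(f, normalizer_id = "A1AG_BOVIN")
  expect_equal(back$mat, qt$mat, tolerance = 1e-12)
  expect_identical(back$normalizer_id, "A1AG_BOVIN")
})
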