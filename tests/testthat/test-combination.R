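test_that("effect-based CI kernels reproduce their defining arithmetic", {
  expect_equal(ci_additivity(0.3, 0.3, 0.6), 1.0)
  expect_equal(ci_additivity(0.2, 0.2, 0.8), 0.5)
  expect_true(is.na(ci_additivity(0.4, 0.4, 0.0)))
  expect_equal(ci_hsa(0.4, 0.6, 0.6), 1.0)
  expect_equal(ci_hsa(0.4, 0.6, 0.9), 2 / 3)
  expect_equal(ci_hsa(0.6, 0.4, 0.3), 2.0)
  expect_equal(ci_bliss(0.5, 0.5, 0.75), 1.0)
  expect_equal(ci_bliss(0.5, 0.5, 0.9), 0.75 / 0.9)
  expect_equal(ci_bliss(1.0, 0.3, 1.0), 1.0)
  expect_error(ci_bliss(1.2, 0.3, 0.5), class = "combindex_validation_error")
})

test_that("Loewe equivalent doses come from curve inversion", {
  f <- dr_fit("log_logistic_01", 1, -1)
  # sham cell: e_ab = fa(2) = 2/3 -> A = B = 2, CI = 1
  sham <- ci_loewe(1, 1, 2 / 3, f, f)
  expect_equal(sham$A, 2, tolerance = 1e-12)
  expect_equal(sham$ci, 1, tolerance = 1e-12)
  # stronger observed effect 0.8 -> A = B = 4, CI = 0.5
  syn <- ci_loewe(1, 1, 0.8, f, f)
  expect_equal(syn$A, 4, tolerance = 1e-12)
  expect_equal(syn$ci, 0.5, tolerance = 1e-12)
  # out-of-range observed effect: strict drops, lenient clamps and flags
  capped <- dr_fit("log_logistic_min0", 1, -1, max_asymptote = 0.8)
  strict <- ci_loewe(1, 1, 0.999999, capped, capped, mode = "strict")
  expect_true(is.na(strict$ci))
  expect_match(strict$reason, "attainable")
  lenient <- ci_loewe(1, 1, 0.999999, capped, capped, mode = "lenient")
  expect_true(lenient$clamped)
  expect_true(is.finite(lenient$ci))
  expect_error(ci_loewe(1, 1, 0.5, f, capped), class = "combindex_validation_error")
})

test_that("ZIP uses curve-expected effects in the Bliss union", {
  f <- dr_fit("log_logistic_01", 1e-8, -1)
  # doses at each Dm -> EE_A = EE_B = 0.5; e_ab at the Bliss expectation -> CI = 1
  z <- ci_zip(1e-8, 1e-8, 0.75, f, f)
  expect_equal(z$ee_a, 0.5); expect_equal(z$ee_b, 0.5)
  expect_equal(z$ci, 1.0)
  expect_equal(ci_zip(1e-8, 1e-8, 0.9, f, f)$ci, 0.75 / 0.9)
  # EE comes from the curve, not the margin data: min-0.2 curve at its Dm
  g <- dr_fit("log_logistic_max1", 1e-8, -1, min_asymptote = 0.2)
  expect_equal(ci_zip(1e-8, 1e-8, 0.9, g, g)$ee_a, 0.6)
})

test_that("classification follows the CI < 1 / = 1 / > 1 rule with an optional band", {
  expect_equal(as.character(classify_ci(0.5)), "synergistic")
  expect_equal(as.character(classify_ci(1.0)), "additive")
  expect_equal(as.character(classify_ci(1.5)), "antagonistic")
  expect_equal(as.character(classify_ci(1.05, band = 0.1)), "additive")
  expect_equal(as.character(classify_ci(NA_real_)), "undefined")
  expect_error(classify_ci(-0.2), class = "combindex_validation_error")
})

test_that("a noiseless Bliss-independent grid scores CI = 1 everywhere under Bliss", {
  sc <- simulation_scenario(drug_a = drug_params("A", Dm = 1e-8),
                            drug_b = drug_params("B", Dm = 4e-8),
                            interaction = "bliss_independent", noise_sd = 0, seed = 5)
  g <- normalize_responses(simulate_combination(sc), "zero_dose")
  ci <- compute_ci_grid(g, "bliss", band = 1e-9)
  expect_equal(nrow(ci), 49)
  expect_lt(max(abs(ci$ci - 1)), 1e-9)
  expect_true(all(ci$classification == "additive"))
})

test_that("a noiseless sham self-combination is Loewe-additive on every cell", {
  sc <- simulation_scenario(drug_a = drug_params("A", Dm = 1e-8, m = -1),
                            drug_b = drug_params("A2", Dm = 5e-8, m = -1),
                            interaction = "loewe_additive_sham", noise_sd = 0, seed = 6)
  g <- normalize_responses(simulate_combination(sc), "zero_dose")
  ci <- compute_ci_grid(g, "loewe", dr_model = "log_logistic_01")
  expect_lt(max(abs(ci$ci - 1)), 1e-4)
  # ZIP on exactly-interpolating fits reduces to Bliss on the margins
  zci <- compute_ci_grid(g, "zip", dr_model = "log_logistic_01")
  eff <- grid_effects(g)
  ea <- eff$effect[eff$dose_b == 0 & eff$dose_a > 0]
  eb <- eff$effect[eff$dose_a == 0 & eff$dose_b > 0]
  interior <- dplyr::filter(eff, dose_a > 0, dose_b > 0)
  bliss_ref <- ci_bliss(ea[match(interior$dose_a, sort(unique(interior$dose_a)))],
                        eb[match(interior$dose_b, sort(unique(interior$dose_b)))],
                        interior$effect)
  expect_equal(sort(zci$ci), sort(bliss_ref), tolerance = 1e-6)
})

test_that("swapping the two drugs leaves every CI model unchanged", {
  sc <- simulation_scenario(drug_a = drug_params("A", Dm = 1e-8, m = -1),
                            drug_b = drug_params("B", Dm = 4e-8, m = -1),
                            interaction = "synergy_kappa", kappa = 3,
                            noise_sd = 0.02, seed = 8)
  g <- normalize_responses(simulate_combination(sc), "zero_dose")
  swapped <- tibble::as_tibble(g) |>
    dplyr::rename(dose_a = dose_b, dose_b = dose_a) |>
    combo_grid(drug_a = attr(g, "drug_b"), drug_b = attr(g, "drug_a"))
  swapped$fa <- dplyr::arrange(tibble::as_tibble(g), dose_b, dose_a, replicate)$fa
  swapped$fa_raw <- dplyr::arrange(tibble::as_tibble(g), dose_b, dose_a, replicate)$fa_raw
  for (model in c("additivity", "hsa", "bliss", "loewe", "zip")) {
    ci1 <- compute_ci_grid(g, model, dr_model = "log_logistic_01")
    ci2 <- compute_ci_grid(swapped, model, dr_model = "log_logistic_01")
    merged <- dplyr::inner_join(
      tibble::as_tibble(ci1)[, c("dose_a", "dose_b", "ci")],
      tibble::as_tibble(ci2)[, c("dose_b", "dose_a", "ci")],
      by = c(dose_a = "dose_b", dose_b = "dose_a"))
    expect_equal(merged$ci.x, merged$ci.y, tolerance = 1e-9,
                 label = paste("symmetry under", model))
  }
})

test_that("HSA and Bliss references never exceed response additivity", {
  set.seed(77)
  n <- 1000
  ea <- runif(n); eb <- runif(n); eab <- runif(n, 0.05, 1)
  add <- ci_additivity(ea, eb, eab)
  expect_true(all(ci_hsa(ea, eb, eab) <= add + 1e-12))
  expect_true(all(ci_bliss(ea, eb, eab) <= add + 1e-12))
})

test_that("dr_model='auto' picks the best mean margin R-squared and is recorded", {
  sc <- simulation_scenario(drug_a = drug_params("A", Dm = 1e-8, m = -1),
                            drug_b = drug_params("B", Dm = 4e-8, m = -1),
                            interaction = "bliss_independent", noise_sd = 0.01, seed = 9)
  g <- normalize_responses(simulate_combination(sc), "zero_dose")
  ci <- compute_ci_grid(g, "loewe", dr_model = "auto")
  expect_true(attr(ci, "dr_model") %in% dr_models())
  expect_s3_class(attr(ci, "fits")$a, "dr_fit")
  gl <- glance(ci)
  expect_equal(gl$n_cells, 49)
})

test_that("margin fit failure is reported with the drug name", {
  # two nonzero doses per axis: too few to fit any curve
  tbl <- tidyr::expand_grid(dose_a = c(0, 1e-9, 1e-8), dose_b = c(0, 1e-9, 1e-8),
                            replicate = 1:3)
  set.seed(1); tbl$response <- 1000 - 500 * (tbl$dose_a + tbl$dose_b > 0) + rnorm(nrow(tbl))
  g <- normalize_responses(combo_grid(tbl, "left", "right"), "zero_dose")
  expect_error(compute_ci_grid(g, "loewe", dr_model = "log_logistic_01"),
               class = "combindex_validation_error", regexp = "left")
})
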