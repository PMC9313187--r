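test_that("long layout reads every replicate row into one dataset per drug", {
  tbl <- clean_plate("HHT")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl[, c("drug", "dose", "replicate", "response")], path)
  d <- read_single_drug_table(path)
  expect_s3_class(d, "dr_data")
  expect_equal(nrow(d), 24)  # (7 doses + control) x 3 reps
  expect_equal(sum(d$dose > 0), 21)
  expect_false(is.unsorted(d$dose))
})

test_that("wide paired dose/response files produce matching datasets", {
  doses <- tibble::tibble(drug = c("A", "B"), dose_1 = c(1e-9, 2e-9),
                          dose_2 = c(1e-8, 2e-8), dose_3 = c(1e-7, 2e-7))
  resp <- tidyr::expand_grid(drug = c("A", "B"), replicate = 1:2) |>
    dplyr::mutate(response_1 = 900, response_2 = 500, response_3 = 100)
  dp <- withr::local_tempfile(fileext = ".csv")
  rp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(doses, dp); readr::write_csv(resp, rp)
  d <- read_single_drug_table(dp, layout = "wide", response_path = rp)
  expect_setequal(unique(d$drug), c("A", "B"))
  expect_equal(nrow(d), 12)
  expect_equal(sort(unique(d$dose[d$drug == "B"])), c(2e-9, 2e-8, 2e-7))
})

test_that("schema and validation errors name the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(drug = "X", dose = 1e-9, response = 5), path)
  expect_error(read_single_drug_table(path), class = "combindex_schema_error",
               regexp = "replicate")
  bad <- clean_plate(); bad$dose[4] <- -1e-9
  readr::write_csv(bad[, c("drug", "dose", "replicate", "response")], path)
  expect_error(read_single_drug_table(path), class = "combindex_validation_error",
               regexp = "row")
})

test_that("duplicated doses merge as extra replicates, sorted ascending", {
  d <- dr_data(tibble::tibble(drug = "X", dose = c(1e-8, 1e-9, 1e-8),
                              replicate = 1, response = c(5, 6, 7)))
  expect_equal(d$dose, c(1e-9, 1e-8, 1e-8))
  expect_equal(d$replicate, c(1L, 1L, 2L))
})

test_that("single-drug write/read round-trips bit-identically", {
  set.seed(11)
  tbl <- clean_plate()
  tbl$response <- tbl$response + rnorm(nrow(tbl), 0, 13.7)
  d <- dr_data(tbl)
  path <- withr::local_tempfile(fileext = ".csv")
  write_single_drug_table(d, path)
  d2 <- read_single_drug_table(path)
  expect_identical(d2$dose, d$dose)
  expect_identical(d2$response, d$response)
})

test_that("matrix dialect reads an 8x8 plate and round-trips exactly", {
  sc <- simulation_scenario(drug_a = drug_params("A"), drug_b = drug_params("B", Dm = 3e-8),
                            seed = 3)
  g <- simulate_combination(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_combination_matrix(g, path)
  g2 <- read_combination_matrix(path, drug_a = "A", drug_b = "B")
  expect_equal(dplyr::n_distinct(g2$dose_a), 8)
  expect_equal(sum(g2$dose_a > 0 & g2$dose_b > 0 & g2$replicate == 1), 49)
  expect_identical(g2$response, g$response)
  expect_identical(g2$dose_a, g$dose_a)
})

test_that("minimal 2x2 matrix yields one interior cell; missing zero column fails", {
  lines <- c(",0,1e-8", "0,100;101,60", "1e-8,55;54,20;21;19")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path)
  expect_message(g <- read_combination_matrix(path), "Ragged")
  expect_equal(nrow(dplyr::filter(g, dose_a > 0, dose_b > 0)), 3)  # ragged cell
  bad <- c(",1e-9,1e-8", "0,1;1,2;2", "1e-8,3;3,4;4")
  writeLines(bad, path)
  expect_error(read_combination_matrix(path), class = "combindex_validation_error",
               regexp = "dose-0")
})

test_that("zero_dose normalisation gives fa = 1 - signal/control, clipped with flags", {
  d <- dr_data(tibble::tibble(drug = "X", dose = c(0, 0, 1e-8, 1e-7),
                              replicate = 1, response = c(200, 200, 50, 220)))
  n <- normalize_responses(d, "zero_dose")
  expect_equal(n$fa[n$dose == 1e-8], 0.75)
  expect_equal(n$fa[n$dose == 0], c(0, 0))
  # 220 = 110% of the reference -> raw fa -0.10, clipped to 0 and flagged
  expect_equal(n$fa_raw[n$dose == 1e-7], -0.10)
  expect_equal(n$fa[n$dose == 1e-7], 0)
  expect_true(n$fa_clipped[n$dose == 1e-7])
  expect_false(any(n$fa_clipped[n$dose < 1e-7]))
})

test_that("normalisation is invariant to rescaling the raw signal", {
  tbl <- clean_plate()
  set.seed(5); tbl$response <- tbl$response + rnorm(nrow(tbl), 0, 20)
  for (method in c("zero_dose", "max_response")) {
    f1 <- normalize_responses(dr_data(tbl), method)$fa_raw
    tbl2 <- tbl; tbl2$response <- tbl2$response * 37.5
    f2 <- normalize_responses(dr_data(tbl2), method)$fa_raw
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("normalisation failure modes raise typed errors", {
  no_zero <- dr_data(tibble::tibble(drug = "X", dose = c(1e-9, 1e-8, 1e-7),
                                    replicate = 1, response = c(3, 2, 1)))
  expect_error(normalize_responses(no_zero, "zero_dose"),
               class = "combindex_normalization_error")
  neg_ref <- dr_data(tibble::tibble(drug = "X", dose = c(0, 1e-8), replicate = 1,
                                    response = c(-5, 1)))
  expect_error(normalize_responses(neg_ref, "zero_dose"),
               class = "combindex_normalization_error")
  not_fa <- dr_data(tibble::tibble(drug = "X", dose = c(0, 1e-8), replicate = 1,
                                   response = c(0.2, 7)))
  expect_error(normalize_responses(not_fa, "none"),
               class = "combindex_normalization_error")
})

test_that("grid margins re-extracted as datasets match the embedded single-drug data", {
  sc <- simulation_scenario(drug_a = drug_params("A"), drug_b = drug_params("B", Dm = 3e-8),
                            noise_sd = 0, seed = 2)
  g <- normalize_responses(simulate_combination(sc), "zero_dose")
  ma <- grid_margin(g, "a")
  expect_s3_class(ma, "dr_data")
  expect_equal(unique(ma$drug), "A")
  truth <- predict_effect(as_dr_fit(sc$drug_a), sort(unique(ma$dose[ma$dose > 0])))
  got <- dplyr::filter(ma, dose > 0) |> dplyr::group_by(dose) |>
    dplyr::summarise(fa = mean(fa)) |> dplyr::pull(fa)
  expect_equal(got, truth, tolerance = 1e-12)
  # control cell of the normalised grid sits at zero effect
  eff <- grid_effects(g)
  expect_equal(eff$effect[eff$dose_a == 0 & eff$dose_b == 0], 0, tolerance = 1e-12)
})
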