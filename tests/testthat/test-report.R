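test_that("analysis_config round-trips losslessly through JSON", {
  cfg <- analysis_config(normalization = "max_response", outlier_threshold = 0.01,
                         dr_model = "log_logistic_4", ci_model = "zip",
                         range_mode = "strict", band = 0.05,
                         output_dir = "somewhere", formats = c("csv", "pdf"),
                         dose_unit = "nM", seed = 99L)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  expect_identical(read_config(path), cfg)
  # the outlier screen can be switched off and survives the round trip
  cfg_off <- analysis_config(outlier_threshold = NULL)
  write_config(cfg_off, path)
  expect_null(read_config(path)$outlier_threshold)
  expect_error(analysis_config(outlier_threshold = 1.2),
               class = "combindex_validation_error")
})

test_that("single-drug workflow writes fit tables, curves and one figure per drug", {
  dir <- withr::local_tempdir()
  two <- dplyr::bind_rows(clean_plate("HHT", Dm = 1.5e-8),
                          clean_plate("ABT", Dm = 7e-6))
  input <- file.path(dir, "plate.csv")
  readr::write_csv(two[, c("drug", "dose", "replicate", "response")], input)
  cfg <- analysis_config(output_dir = file.path(dir, "out"),
                         formats = c("csv", "png"), outlier_threshold = NULL)
  res <- run_single_analysis(input, cfg)
  expect_equal(nrow(res$fits), 10)  # 2 drugs x 5 models
  expect_true(file.exists(file.path(dir, "out", "fit_table.csv")))
  expect_true(file.exists(file.path(dir, "out", "fit_overlay_HHT.png")))
  expect_true(file.exists(file.path(dir, "out", "fit_overlay_ABT.png")))
  # the CSV twin holds exactly the plotted curve numbers
  curves <- readr::read_csv(file.path(dir, "out", "curve_table.csv"),
                            show_col_types = FALSE)
  expect_equal(nrow(curves), nrow(res$curves))
  expect_equal(curves$fa, res$curves$fa, tolerance = 1e-12)
})

test_that("csv-only format writes no images; outlier flag controls the audit trail", {
  dir <- withr::local_tempdir()
  tbl <- clean_plate("X")
  set.seed(4); tbl$response <- tbl$response + rnorm(nrow(tbl), 0, 15)
  tbl$response[which(tbl$dose == sort(unique(tbl$dose))[2])[1]] <- 300  # gross outlier
  input <- file.path(dir, "x.csv")
  readr::write_csv(tbl[, c("drug", "dose", "replicate", "response")], input)
  out1 <- file.path(dir, "csvonly")
  res <- run_single_analysis(input, analysis_config(output_dir = out1,
                                                    formats = "csv",
                                                    outlier_threshold = 0.05))
  expect_length(list.files(out1, pattern = "\\.png$"), 0)
  expect_true(file.exists(file.path(out1, "outlier_audit.csv")))
  out2 <- file.path(dir, "noscreen")
  res2 <- run_single_analysis(input, analysis_config(output_dir = out2,
                                                     formats = "csv",
                                                     outlier_threshold = NULL))
  expect_false(file.exists(file.path(out2, "outlier_audit.csv")))
})

test_that("comparison workflow overlays samples and rejects too many inputs", {
  dir <- withr::local_tempdir()
  paths <- purrr::map_chr(1:2, function(i) {
    p <- file.path(dir, paste0("s", i, ".csv"))
    tbl <- clean_plate("X", Dm = c(7e-9, 9e-9)[i])
    readr::write_csv(tbl[, c("drug", "dose", "replicate", "response")], p)
    p
  })
  cfg <- analysis_config(output_dir = file.path(dir, "cmp"), formats = "csv",
                         dr_model = "log_logistic_01", outlier_threshold = NULL)
  res <- run_compare_analysis(paths, cfg)
  expect_equal(nrow(res$comparison$fits), 2)
  expect_true(file.exists(file.path(dir, "cmp", "compare_fits.csv")))
  expect_error(run_compare_analysis(rep(paths[1], 5), cfg),
               class = "combindex_validation_error")
})

test_that("combination workflow exports heatmap, CI table and PDF report", {
  dir <- withr::local_tempdir()
  sc <- simulation_scenario(drug_a = drug_params("A", Dm = 1e-8, m = -1),
                            drug_b = drug_params("B", Dm = 4e-8, m = -1),
                            interaction = "loewe_additive_sham",
                            noise_sd = 0.01, seed = 12)
  files <- run_simulation(sc, file.path(dir, "sim"))
  expect_true(file.exists(files[["matrix"]]))
  expect_true(file.exists(files[["sidecar"]]))
  cfg <- analysis_config(output_dir = file.path(dir, "combo"),
                         formats = c("csv", "png", "pdf"), ci_model = "loewe",
                         dr_model = "log_logistic_01", band = 0.05)
  res <- run_combo_analysis(files[["matrix"]], cfg, drug_a = "A", drug_b = "B")
  for (f in c("inhibition_table.csv", "ci_table.csv", "margin_fit_table.csv",
              "inhibition_heatmap.png", "ci_plot.png", "combination_report.pdf")) {
    expect_true(file.exists(file.path(dir, "combo", f)), label = f)
  }
  # low-noise sham: the CI surface centres on additivity (individual cells
  # near the upper asymptote are noise-amplified by the curve inversion)
  expect_lt(abs(median(res$ci$ci, na.rm = TRUE) - 1), 0.1)
  expect_true(all(levels(res$ci$classification) ==
                    c("synergistic", "additive", "antagonistic", "undefined")))
  ci_tbl <- readr::read_csv(file.path(dir, "combo", "ci_table.csv"),
                            show_col_types = FALSE)
  expect_equal(nrow(ci_tbl), nrow(res$ci))
})

test_that("fixed inputs and config give byte-identical CSV outputs across runs", {
  dir <- withr::local_tempdir()
  sc <- simulation_scenario(drug_a = drug_params("A"), drug_b = drug_params("B", Dm = 3e-8),
                            seed = 33)
  f1 <- run_simulation(sc, file.path(dir, "r1"))
  f2 <- run_simulation(sc, file.path(dir, "r2"))
  expect_identical(readLines(f1[["matrix"]]), readLines(f2[["matrix"]]))
  cfg1 <- analysis_config(output_dir = file.path(dir, "o1"), formats = "csv")
  cfg2 <- analysis_config(output_dir = file.path(dir, "o2"), formats = "csv")
  run_combo_analysis(f1[["matrix"]], cfg1)
  run_combo_analysis(f2[["matrix"]], cfg2)
  expect_identical(readLines(file.path(dir, "o1", "ci_table.csv")),
                   readLines(file.path(dir, "o2", "ci_table.csv")))
})
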