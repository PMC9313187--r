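#' Analysis configuration
#'
#' Bundles every user-tunable option of the pipeline. The object
#' round-trips losslessly through JSON ([write_config()] /
#' [read_config()]) so an analysis can be reproduced from its sidecar.
#'
#' @param normalization One of `"zero_dose"`, `"max_response"`, `"none"`.
#' @param outlier_threshold Grubbs p-value threshold in (0, 1), or `NULL`
#'   to switch the screen off.
#' @param dr_model Dose-response model name or `"auto"` (best mean
#'   R-squared across the margins).
#' @param ci_model One of [ci_models()].
#' @param range_mode Loewe out-of-range handling: `"lenient"`/`"strict"`.
#' @param band Additivity classification half-width.
#' @param output_dir Directory for exports.
#' @param formats Subset of `c("csv", "png", "pdf")`.
#' @param dose_unit Unit label used in outputs (doses are molar; no
#'   conversion is performed).
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(normalization = "zero_dose",
                            outlier_threshold = 0.05,
                            dr_model = "auto", ci_model = "loewe",
                            range_mode = "lenient", band = 0,
                            output_dir = ".", formats = c("csv", "png"),
                            dose_unit = "M", seed = 1L) {
  normalization <- arg_match(normalization, c("zero_dose", "max_response", "none"))
  if (!is.null(outlier_threshold)) check_threshold(outlier_threshold)
  if (!identical(dr_model, "auto")) dr_model <- arg_match(dr_model, dr_models())
  ci_model <- arg_match(ci_model, ci_models())
  range_mode <- arg_match(range_mode, c("lenient", "strict"))
  formats <- arg_match(formats, c("csv", "png", "pdf"), multiple = TRUE)
  structure(list(normalization = normalization,
                 outlier_threshold = outlier_threshold,
                 dr_model = dr_model, ci_model = ci_model,
                 range_mode = range_mode, band = band,
                 output_dir = output_dir, formats = formats,
                 dose_unit = dose_unit, seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config An `analysis_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

prep_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

save_plot <- function(p, stem, config, width = 7, height = 5) {
  files <- character(0)
  if ("png" %in% config$formats) {
    f <- file.path(config$output_dir, paste0(stem, ".png"))
    grDevices::png(f, width = width * 100, height = height * 100, res = 110)
    print(p); grDevices::dev.off()
    files <- c(files, f)
  }
  files
}

write_tbl <- function(tbl, stem, config) {
  if (!"csv" %in% config$formats) return(character(0))
  f <- file.path(config$output_dir, paste0(stem, ".csv"))
  readr::write_csv(tbl, f, progress = FALSE)
  f
}

prep_single <- function(input, config) {
  data <- if (is.character(input)) read_single_drug_table(input) else dr_data(input)
  data <- normalize_responses(data, config$normalization)
  report <- NULL
  if (!is.null(config$outlier_threshold)) {
    scr <- remove_outliers(data, config$outlier_threshold)
    data <- scr$data; report <- scr$report
  }
  list(data = data, outlier_report = report)
}

flat_fit_table <- function(fits) {
  fits %>% select(-all_of("fit")) %>%
    select(dplyr::any_of(c("sample", "drug", "model", "Dm", "m", "min_asymptote",
                           "max_asymptote", "r_squared", "ic50", "ic50_note",
                           "n_points", "converged", "rank", "error")))
}

#' Run the single-drug analysis workflow
#'
#' Reads (or takes) a plate table, normalises, optionally screens
#' outliers, fits all five dose-response models per drug, and exports a
#' fit table, dense curve tables, the outlier audit trail and a
#' five-model overlay figure per drug.
#'
#' @param input Path to a long-layout CSV, or a [dr_data()] tibble.
#' @param config An [analysis_config()].
#' @return Invisibly, a list: `data`, `fits`, `curves`, `outlier_report`,
#'   `files` (paths written).
#' @export
run_single_analysis <- function(input, config = analysis_config()) {
  prep_dir(config$output_dir)
  pre <- prep_single(input, config)
  fits <- fit_all_models(pre$data)
  curves <- fits %>% filter(!purrr::map_lgl(.data$fit, is.null)) %>%
    pull("fit") %>% purrr::map(curve_table) %>% bind_rows()
  files <- c(write_tbl(flat_fit_table(fits), "fit_table", config),
             write_tbl(curves, "curve_table", config))
  if (!is.null(pre$outlier_report) && nrow(pre$outlier_report) > 0) {
    files <- c(files, write_tbl(pre$outlier_report, "outlier_audit", config))
  }
  plots <- list()
  for (dg in unique(fits$drug)) {
    p <- plot_fit_overlay(fits %>% filter(.data$drug == dg), pre$data,
                          dose_unit = config$dose_unit)
    plots[[dg]] <- p
    files <- c(files, save_plot(p, paste0("fit_overlay_", make.names(dg)), config))
  }
  if ("pdf" %in% config$formats) {
    f <- file.path(config$output_dir, "single_drug_report.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    for (p in plots) print(p)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(list(data = pre$data, fits = fits, curves = curves,
                 outlier_report = pre$outlier_report, files = files))
}

#' Run the multi-sample comparison workflow
#'
#' Overlays 2-4 samples of the same drug(s) under one shared model.
#'
#' @param inputs Character vector of 2-4 CSV paths, or list of 2-4
#'   [dr_data()] tibbles (names become sample labels).
#' @param config An [analysis_config()]; `dr_model = "auto"` resolves to
#'   the model with the best mean R-squared over all samples.
#' @return Invisibly: `comparison` (see [compare_samples()]) and `files`.
#' @export
run_compare_analysis <- function(inputs, config = analysis_config()) {
  if (length(inputs) < 2 || length(inputs) > 4) {
    abort_validation("Comparison needs between 2 and 4 input samples.")
  }
  prep_dir(config$output_dir)
  if (is.character(inputs)) {
    nm <- sub("\\.csv$", "", basename(inputs))
    inputs <- setNames(lapply(inputs, identity), make.unique(nm))
  }
  datasets <- purrr::map(inputs, function(x) prep_single(x, config)$data)
  model <- config$dr_model
  if (identical(model, "auto")) {
    mean_r2 <- purrr::map(datasets, fit_all_models) %>% bind_rows() %>%
      group_by(.data$model) %>%
      summarise(m = mean(.data$r_squared, na.rm = TRUE), .groups = "drop") %>%
      filter(is.finite(.data$m))
    model <- mean_r2$model[which.max(mean_r2$m)]
  }
  cmp <- compare_samples(datasets, model)
  files <- c(write_tbl(flat_fit_table(cmp$fits), "compare_fits", config),
             write_tbl(cmp$curves, "compare_curves", config),
             save_plot(autoplot(cmp, dose_unit = config$dose_unit),
                       "compare_overlay", config))
  if ("pdf" %in% config$formats) {
    f <- file.path(config$output_dir, "compare_report.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    print(autoplot(cmp, dose_unit = config$dose_unit))
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(list(comparison = cmp, files = files))
}

#' Run the combination analysis workflow
#'
#' Reads (or takes) a checkerboard matrix, normalises, optionally screens
#' outliers per cell, computes the CI grid, and exports: the inhibition
#' heatmap, the CI bubble plot, both margins' five-model fit tables and
#' overlay figures, the CI table CSV, and (optionally) a multi-page PDF
#' report bundling all panels. If the margin fits fail, the CI section is
#' marked unavailable instead of aborting the report.
#'
#' @param input Path to a matrix CSV, or a [combo_grid()].
#' @param config An [analysis_config()].
#' @param drug_a,drug_b Axis drug names used when `input` is a path.
#' @return Invisibly: `grid`, `ci` (or `NULL` on margin failure),
#'   `margin_fits`, `outlier_report`, `files`.
#' @export
run_combo_analysis <- function(input, config = analysis_config(),
                               drug_a = "drug_A", drug_b = "drug_B") {
  prep_dir(config$output_dir)
  grid <- if (is.character(input)) {
    read_combination_matrix(input, drug_a = drug_a, drug_b = drug_b)
  } else input
  stopifnot(inherits(grid, "combo_grid"))
  grid <- normalize_responses(grid, config$normalization)
  report <- NULL
  if (!is.null(config$outlier_threshold)) {
    scr <- remove_outliers(grid, config$outlier_threshold)
    grid <- scr$data; report <- scr$report
  }
  files <- c(write_tbl(grid_effects(grid), "inhibition_table", config),
             save_plot(plot_inhibition_heatmap(grid, config$dose_unit),
                       "inhibition_heatmap", config))
  if (!is.null(report) && nrow(report) > 0) {
    files <- c(files, write_tbl(report, "outlier_audit", config))
  }
  margin_fits <- bind_rows(fit_all_models(grid_margin(grid, "a")),
                           fit_all_models(grid_margin(grid, "b")))
  files <- c(files, write_tbl(flat_fit_table(margin_fits), "margin_fit_table", config))
  ci <- tryCatch(
    compute_ci_grid(grid, ci_model = config$ci_model, dr_model = config$dr_model,
                    mode = config$range_mode, band = config$band),
    error = function(e) {
      warn(paste0("CI section unavailable: ", conditionMessage(e)))
      NULL
    })
  plots <- list(heatmap = plot_inhibition_heatmap(grid, config$dose_unit))
  for (side in c("a", "b")) {
    dg <- attr(grid, paste0("drug_", side))
    p <- plot_fit_overlay(margin_fits %>% filter(.data$drug == dg),
                          grid_margin(grid, side), dose_unit = config$dose_unit)
    plots[[paste0("margin_", side)]] <- p
    files <- c(files, save_plot(p, paste0("margin_fit_", make.names(dg)), config))
  }
  if (!is.null(ci)) {
    ci_tbl <- as_tibble(ci) %>%
      mutate(ci_model = attr(ci, "ci_model"), dr_model = attr(ci, "dr_model"))
    files <- c(files, write_tbl(ci_tbl, "ci_table", config),
               save_plot(autoplot(ci, dose_unit = config$dose_unit), "ci_plot", config))
    plots$ci <- autoplot(ci, dose_unit = config$dose_unit)
  }
  if ("pdf" %in% config$formats) {
    f <- file.path(config$output_dir, "combination_report.pdf")
    grDevices::pdf(f, width = 7, height = 5)
    for (p in plots) print(p)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(list(grid = grid, ci = ci, margin_fits = margin_fits,
                 outlier_report = report, files = files))
}

#' Generate synthetic plate files from a scenario
#'
#' Writes a combination matrix CSV, one single-drug CSV per drug, and a
#' JSON sidecar with the true parameters and the true CI surface —
#' everything the other workflows can read back.
#'
#' @param scenario A [simulation_scenario()] (with `drug_b` for grids).
#' @param output_dir Output directory.
#' @return Invisibly, the named vector of files written.
#' @export
run_simulation <- function(scenario, output_dir = ".") {
  stopifnot(inherits(scenario, "simulation_scenario"))
  prep_dir(output_dir)
  files <- c()
  da <- simulate_single_drug(scenario, "a")
  fa_path <- file.path(output_dir, paste0(scenario$drug_a$name, "_single.csv"))
  write_single_drug_table(da, fa_path)
  files["single_a"] <- fa_path
  sidecar <- list(scenario = list(
    drug_a = unclass(scenario$drug_a), drug_b = if (!is.null(scenario$drug_b)) unclass(scenario$drug_b),
    n_doses = scenario$n_doses, dose_factor = scenario$dose_factor,
    replicates = scenario$replicates, noise_sd = scenario$noise_sd,
    reference_signal = scenario$reference_signal,
    outlier_n = scenario$outlier_n, outlier_sd = scenario$outlier_sd,
    interaction = scenario$interaction, kappa = scenario$kappa,
    seed = scenario$seed))
  if (!is.null(scenario$drug_b)) {
    db <- simulate_single_drug(scenario, "b")
    fb_path <- file.path(output_dir, paste0(scenario$drug_b$name, "_single.csv"))
    write_single_drug_table(db, fb_path)
    files["single_b"] <- fb_path
    grid <- simulate_combination(scenario)
    m_path <- file.path(output_dir, "combination_matrix.csv")
    write_combination_matrix(grid, m_path)
    files["matrix"] <- m_path
    truth_model <- switch(scenario$interaction,
                          bliss_independent = "bliss", "loewe")
    truth <- true_ci_surface(scenario, truth_model)
    sidecar$true_ci <- list(model = truth_model, surface = truth)
  }
  sc_path <- file.path(output_dir, "scenario.json")
  jsonlite::write_json(sidecar, sc_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  files["sidecar"] <- sc_path
  invisible(files)
}
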