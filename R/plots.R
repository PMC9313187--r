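# ggplot2 views of results. Every figure has a CSV twin produced by the
# run_* wrappers; these functions only draw numbers that already exist in
# a tibble.

#' Five-model overlay plot for one drug
#'
#' Observed replicate fa points, the fitted curve of every model that
#' converged, and a vertical marker at each model's IC50.
#'
#' @param fits A [fit_all_models()] table filtered to one drug.
#' @param data The normalised [dr_data()] behind the fits.
#' @param dose_unit Axis unit label.
#' @return A ggplot object.
#' @export
plot_fit_overlay <- function(fits, data, dose_unit = "M") {
  stopifnot(is.data.frame(fits))
  drug_name <- unique(fits$drug)
  if (length(drug_name) != 1) abort_validation("`fits` must cover exactly one drug.")
  pts <- fit_points(data, drug_name)
  ok <- fits %>% filter(!purrr::map_lgl(.data$fit, is.null))
  curves <- purrr::map(ok$fit, curve_table) %>% bind_rows()
  ic_marks <- ok %>% filter(is.finite(.data$ic50))
  lab <- function(x) scales::scientific(x)
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$dose, y = .data$fa_raw),
                        colour = "grey30", alpha = 0.7) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$dose, y = .data$fa, colour = .data$model)) +
    ggplot2::scale_x_log10(labels = lab) +
    ggplot2::labs(title = drug_name,
                  x = paste0("dose (", dose_unit, ", log scale)"),
                  y = "fraction affected", colour = "model") +
    ggplot2::theme_minimal()
  if (nrow(ic_marks) > 0) {
    p <- p + ggplot2::geom_vline(data = ic_marks,
                                 ggplot2::aes(xintercept = .data$ic50,
                                              colour = .data$model),
                                 linetype = "dashed", alpha = 0.6)
  }
  p
}

#' Inhibition heatmap of a checkerboard grid
#'
#' Mean fraction affected per cell over the full matrix, margins included.
#'
#' @param grid A normalised [combo_grid()].
#' @param dose_unit Axis unit label.
#' @return A ggplot object.
#' @export
plot_inhibition_heatmap <- function(grid, dose_unit = "M") {
  eff <- grid_effects(grid)
  eff <- eff %>% mutate(fa_lab = factor(num_chr(.data$dose_a), levels = num_chr(sort(unique(.data$dose_a)))),
                        fb_lab = factor(num_chr(.data$dose_b), levels = num_chr(sort(unique(.data$dose_b)))))
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$fa_lab, y = .data$fb_lab,
                                    fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "inhibition") +
    ggplot2::labs(x = paste0(attr(grid, "drug_a"), " dose (", dose_unit, ")"),
                  y = paste0(attr(grid, "drug_b"), " dose (", dose_unit, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Combination-index bubble plot
#'
#' One bubble per interior cell: area proportional to `|log10(CI)|` so
#' synergy and antagonism scale symmetrically, colour by classification.
#'
#' @param ci A `ci_grid` from [compute_ci_grid()].
#' @param dose_unit Axis unit label.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ci_grid <- function(object, dose_unit = "M", ...) {
  dat <- as_tibble(object) %>%
    mutate(power = abs(log10(.data$ci)),
           fa_lab = factor(num_chr(.data$dose_a), levels = num_chr(sort(unique(.data$dose_a)))),
           fb_lab = factor(num_chr(.data$dose_b), levels = num_chr(sort(unique(.data$dose_b)))))
  cols <- c(synergistic = "#2166ac", additive = "grey55",
            antagonistic = "#b2182b", undefined = "grey85")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fa_lab, y = .data$fb_lab)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$power,
                                     colour = .data$classification), alpha = 0.85) +
    ggplot2::scale_size_area(max_size = 10, name = "|log10 CI|") +
    ggplot2::scale_colour_manual(values = cols, drop = FALSE) +
    ggplot2::labs(title = sprintf("%s combination index", attr(object, "ci_model")),
                  x = paste0(attr(object, "drug_a"), " dose (", dose_unit, ")"),
                  y = paste0(attr(object, "drug_b"), " dose (", dose_unit, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.dr_fit <- function(object, ...) {
  curves <- curve_table(object)
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = curves, ggplot2::aes(x = .data$dose, y = .data$fa)) +
    ggplot2::scale_x_log10(labels = scales::scientific) +
    ggplot2::labs(title = sprintf("%s (%s)", object$drug, object$model),
                  x = "dose (log scale)", y = "fraction affected") +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data,
                                 ggplot2::aes(x = .data$dose, y = .data$fa_raw),
                                 colour = "grey30", alpha = 0.7)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.dr_comparison <- function(object, dose_unit = "M", ...) {
  pts <- NULL
  ggplot2::ggplot() +
    ggplot2::geom_line(data = object$curves,
                       ggplot2::aes(x = .data$dose, y = .data$fa,
                                    colour = .data$sample)) +
    ggplot2::facet_wrap(~drug) +
    ggplot2::scale_x_log10(labels = scales::scientific) +
    ggplot2::labs(title = sprintf("model: %s", object$model),
                  x = paste0("dose (", dose_unit, ", log scale)"),
                  y = "fraction affected", colour = "sample") +
    ggplot2::theme_minimal()
}
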