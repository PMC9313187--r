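# Model fitting: the median-effect linearisation and bounded
# Levenberg-Marquardt NLS for the log-logistic family.

fit_points <- function(data, drug = NULL) {
  tbl <- as_tibble(data)
  if (!is.null(drug)) tbl <- tbl %>% filter(.data$drug == !!drug)
  if (dplyr::n_distinct(tbl$drug) > 1) {
    abort_validation("Data contain several drugs; pass `drug` to pick one.")
  }
  if (is.null(tbl[["fa_raw"]])) {
    abort_validation("No fa values; run normalize_responses() first.")
  }
  tbl %>% filter(.data$dose > 0) %>%
    select(all_of(c("drug", "dose", "fa", "fa_raw")))
}

min_doses_for <- function(model) if (model == "log_logistic_4") 4L else 3L

# Linearisation of the median-effect equation:
# log(fa/(1-fa)) = m*log(D) - m*log(Dm). Replicate fa outside (0, 1) cannot
# enter the logit and is excluded; the rest is clamped to [eps, 1-eps].
fit_median_effect <- function(pts, eps = 1e-6) {
  usable <- pts %>% filter(.data$fa_raw > 0, .data$fa_raw < 1)
  if (dplyr::n_distinct(usable$dose) < 3) {
    abort_insufficient("median_effect needs >= 3 distinct nonzero doses with fa inside (0, 1).")
  }
  fa <- clamp(usable$fa_raw, eps, 1 - eps)
  y <- log(fa / (1 - fa))
  x <- log(usable$dose)
  ols <- lm(y ~ x)
  m <- unname(coef(ols)[2])
  if (!is.finite(m) || m == 0) abort_degenerate("Degenerate median-effect regression (zero slope).")
  Dm <- exp(-unname(coef(ols)[1]) / m)
  list(Dm = Dm, m = m, min = 0, max = 1, converged = TRUE)
}

ll_formula <- function(model) {
  switch(model,
    log_logistic_01 = fa_raw ~ 1 / (1 + exp(m * (log(dose) - lDm))),
    log_logistic_min0 = fa_raw ~ hi / (1 + exp(m * (log(dose) - lDm))),
    log_logistic_max1 = fa_raw ~ lo + (1 - lo) / (1 + exp(m * (log(dose) - lDm))),
    log_logistic_4 = fa_raw ~ lo + (hi - lo) / (1 + exp(m * (log(dose) - lDm))))
}

ll_bounds <- function(model, ld_range) {
  lower <- c(lDm = ld_range[1], m = -20)
  upper <- c(lDm = ld_range[2], m = 20)
  if (model %in% c("log_logistic_min0", "log_logistic_4")) {
    lower <- c(lower, hi = -0.5); upper <- c(upper, hi = 1.5)
  }
  if (model %in% c("log_logistic_max1", "log_logistic_4")) {
    lower <- c(lower, lo = -0.5); upper <- c(upper, lo = 1.5)
  }
  list(lower = lower, upper = upper)
}

fit_log_logistic <- function(pts, model) {
  if (dplyr::n_distinct(pts$dose) < min_doses_for(model)) {
    abort_insufficient(sprintf("%s needs >= %d distinct nonzero doses.",
                               model, min_doses_for(model)))
  }
  dose_means <- pts %>% group_by(.data$dose) %>%
    summarise(fa = mean(.data$fa_raw), .groups = "drop") %>% arrange(.data$dose)
  half <- (min(dose_means$fa) + max(dose_means$fa)) / 2
  Dm0 <- dose_means$dose[which.min(abs(dose_means$fa - half))]
  # log-logistic convention: fa rises with dose for m < 0
  dir <- if (tail(dose_means$fa, 1) >= head(dose_means$fa, 1)) -1 else 1
  ld_range <- c(log(min(pts$dose)) - log(1e6), log(max(pts$dose)) + log(1e6))
  b <- ll_bounds(model, ld_range)
  start_base <- c(lDm = log(Dm0))
  if (model %in% c("log_logistic_min0", "log_logistic_4")) {
    start_base <- c(start_base, hi = clamp(max(dose_means$fa), 0.1, 1.5))
  }
  if (model %in% c("log_logistic_max1", "log_logistic_4")) {
    start_base <- c(start_base, lo = clamp(min(dose_means$fa), -0.5, 0.9))
  }
  form <- ll_formula(model)
  best <- NULL
  for (m0 in dir * c(1, 0.5, 3)) {
    start <- c(start_base[1], m = m0, start_base[-1])
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = pts, start = as.list(start),
                        lower = b$lower[names(start)], upper = b$upper[names(start)],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(residuals(fit)^2)
    conv <- fit$convInfo$isConv %||% TRUE
    if (is.null(best) || ssr < best$ssr - 1e-15) {
      best <- list(fit = fit, ssr = ssr, converged = isTRUE(conv))
    }
    if (!is.null(best) && best$converged) break
  }
  if (is.null(best)) {
    abort_degenerate(sprintf("%s: the nonlinear solver failed from every start.", model))
  }
  cf <- coef(best$fit)
  lo <- unname(cf["lo"] %|na|% 0); hi <- unname(cf["hi"] %|na|% 1)
  m <- unname(cf["m"]); Dm <- exp(unname(cf["lDm"]))
  if (lo > hi) {  # asymptote swap: identical curve with the slope negated
    tmp <- lo; lo <- hi; hi <- tmp; m <- -m
  }
  if (model == "log_logistic_min0") lo <- 0
  if (model == "log_logistic_max1") hi <- 1
  list(Dm = Dm, m = m, min = lo, max = hi, converged = best$converged)
}

`%|na|%` <- function(x, default) if (length(x) == 0 || is.na(x)) default else x

#' Fit one dose-response model to a single-drug dataset
#'
#' The median-effect model is fitted by ordinary least squares on its
#' logit-log linearisation; the log-logistic variants by bounded
#' Levenberg-Marquardt nonlinear least squares on the replicate-level
#' (dose, fa) pairs, with the model's fixed asymptotes substituted.
#' Dose-0 wells never enter a fit (they anchor normalisation only), and
#' fitting uses the unclipped fa values.
#'
#' @param data A normalised [dr_data()] tibble (one drug, or pass `drug`).
#' @param model One of [dr_models()].
#' @param drug Drug to fit when `data` holds several.
#' @return A [dr_fit()] with `r_squared`, `ic50`, `n_points`, `converged`.
#' @export
fit_model <- function(data, model = c("log_logistic_01", "median_effect",
                                      "log_logistic_4", "log_logistic_min0",
                                      "log_logistic_max1"),
                      drug = NULL) {
  model <- arg_match(model, dr_models())
  pts <- fit_points(data, drug)
  if (nrow(pts) == 0) abort_insufficient("No nonzero-dose points to fit.")
  par <- if (model == "median_effect") fit_median_effect(pts) else fit_log_logistic(pts, model)
  fit <- dr_fit(model, Dm = par$Dm, m = par$m,
                min_asymptote = par$min, max_asymptote = par$max,
                drug = pts$drug[1], n_points = nrow(pts), converged = par$converged,
                data = pts)
  fit$r_squared <- r_squared(fit, data)
  fit$ic50 <- ic50(fit)
  fit
}

#' Coefficient of determination of a fit on the fa scale
#'
#' `1 - SS_res / SS_tot` over all nonzero-dose replicate points, with
#' `SS_tot` about the grand mean. Can be negative for a fit worse than a
#' constant; `NA` (with a message) when the observed fa values have zero
#' variance.
#'
#' @param fit A [dr_fit()].
#' @param data The normalised [dr_data()] the fit refers to.
#' @return A single number, or `NA`.
#' @export
r_squared <- function(fit, data) {
  stopifnot(inherits(fit, "dr_fit"))
  pts <- fit_points(data, drug = if (is.na(fit$drug)) NULL else fit$drug)
  obs <- pts$fa_raw
  pred <- predict_effect(fit, pts$dose)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    inform("R^2 undefined: observed fa values have zero variance.")
    return(NA_real_)
  }
  1 - sum((obs - pred)^2) / ss_tot
}

#' Absolute IC50 of a fitted curve
#'
#' The dose giving 50% absolute inhibition (fa = 0.5), i.e.
#' `inverse_dose(fit, 0.5)`, when 0.5 lies inside the curve's attainable
#' range; `NA` with a `"reason"` attribute otherwise. For the models with
#' asymptotes fixed at (0, 1) this equals `Dm` (the relative midpoint
#' `Dm` is always reported separately in fit tables).
#'
#' @param fit A [dr_fit()].
#' @return Dose (molar) or `NA`.
#' @export
ic50 <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  rng <- attainable_range(fit)
  if (0.5 <= rng[1] || 0.5 >= rng[2]) {
    return(structure(NA_real_,
                     reason = sprintf("fa = 0.5 outside attainable range (%g, %g)",
                                      rng[1], rng[2])))
  }
  unname(inverse_dose(fit, 0.5))
}

fit_row <- function(fit) {
  tibble(drug = fit$drug, model = fit$model, Dm = fit$Dm, m = fit$m,
         min_asymptote = fit$min_asymptote, max_asymptote = fit$max_asymptote,
         r_squared = fit$r_squared, ic50 = as.numeric(fit$ic50),
         ic50_note = attr(fit$ic50, "reason", exact = TRUE) %||% NA_character_,
         n_points = fit$n_points, converged = fit$converged,
         fit = list(fit), error = NA_character_)
}

#' Fit all five dose-response models
#'
#' Fits every model in [dr_models()] to each drug in `data` and ranks the
#' fits by R-squared. Per-model failures (e.g. too few doses for the
#' four-parameter curve) are recorded in the `error` column rather than
#' raised.
#'
#' @param data A normalised [dr_data()] tibble (any number of drugs).
#' @return A tibble with one row per drug and model: parameter estimates,
#'   `r_squared`, `ic50`, `rank` (1 = best R-squared within drug) and a
#'   `fit` list-column of [dr_fit()] objects.
#' @export
fit_all_models <- function(data) {
  tbl <- as_tibble(data)
  rows <- purrr::map(split(tbl, tbl$drug), function(d) {
    d <- new_dr_data(d, normalization = attr(data, "normalization", exact = TRUE))
    per_model <- purrr::map(dr_models(), function(mod) {
      res <- tryCatch(fit_model(d, mod), error = function(e) e)
      if (inherits(res, "error")) {
        tibble(drug = d$drug[1], model = mod, Dm = NA_real_, m = NA_real_,
               min_asymptote = NA_real_, max_asymptote = NA_real_,
               r_squared = NA_real_, ic50 = NA_real_, ic50_note = NA_character_,
               n_points = NA_integer_, converged = NA, fit = list(NULL),
               error = conditionMessage(res))
      } else fit_row(res)
    })
    out <- bind_rows(per_model)
    out$rank <- rank(-out$r_squared, ties.method = "min", na.last = "keep")
    out
  })
  bind_rows(rows)
}

#' Dense curve table for plotting a fitted model
#'
#' @param fit A [dr_fit()].
#' @param n Number of grid points.
#' @param dose_range Optional `c(lo, hi)`; defaults to the fitted data's
#'   dose range widened by a factor of 10 on each side.
#' @return Tibble `drug`, `model`, `dose`, `fa` on a log-spaced grid.
#' @export
curve_table <- function(fit, n = 100, dose_range = NULL) {
  stopifnot(inherits(fit, "dr_fit"))
  if (is.null(dose_range)) {
    if (is.null(fit$data)) abort_validation("Fit has no data; supply `dose_range`.")
    dose_range <- c(min(fit$data$dose) / 10, max(fit$data$dose) * 10)
  }
  doses <- exp(seq(log(dose_range[1]), log(dose_range[2]), length.out = n))
  tibble(drug = fit$drug, model = fit$model, dose = doses,
         fa = predict_effect(fit, doses))
}

#' Overlay comparison of the same drug across samples
#'
#' Fits one shared dose-response model to 2-4 datasets (e.g. different
#' cell lines or files) and returns per-sample fits plus dense curves for
#' plotting. Drugs present in only some samples are dropped with a
#' warning; the intersection is analysed.
#'
#' @param datasets Named list of 2-4 normalised [dr_data()] tibbles.
#' @param model Shared model, one of [dr_models()].
#' @return List of class `dr_comparison`: `fits` (tibble of per-sample
#'   parameter rows) and `curves` (sample-labelled [curve_table()] rows).
#' @export
compare_samples <- function(datasets, model = "log_logistic_01") {
  if (!is.list(datasets) || length(datasets) < 2 || length(datasets) > 4) {
    abort_validation("`datasets` must be a list of 2 to 4 datasets.")
  }
  model <- arg_match(model, dr_models())
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- paste0("sample_", seq_along(datasets))
  }
  drug_sets <- purrr::map(datasets, ~ unique(as_tibble(.x)$drug))
  shared <- Reduce(intersect, drug_sets)
  if (length(shared) == 0) abort_validation("The samples share no drug names.")
  if (any(lengths(drug_sets) > length(shared))) {
    warn("Samples do not share all drug names; analysing the intersection only.")
  }
  fits <- list(); curves <- list()
  for (s in names(datasets)) {
    for (dg in shared) {
      f <- fit_model(datasets[[s]], model, drug = dg)
      row <- fit_row(f); row$sample <- s
      fits[[length(fits) + 1L]] <- row
      cv <- curve_table(f); cv$sample <- s
      curves[[length(curves) + 1L]] <- cv
    }
  }
  structure(list(fits = bind_rows(fits) %>% select(all_of("sample"), dplyr::everything()),
                 curves = bind_rows(curves) %>% select(all_of("sample"), dplyr::everything()),
                 model = model),
            class = "dr_comparison")
}

# ---- broom-style methods ----------------------------------------------------

#' @exportS3Method generics::tidy
tidy.dr_fit <- function(x, ...) {
  tibble(term = c("Dm", "m", "min_asymptote", "max_asymptote"),
         estimate = c(x$Dm, x$m, x$min_asymptote, x$max_asymptote))
}

#' @exportS3Method generics::glance
glance.dr_fit <- function(x, ...) {
  tibble(model = x$model, drug = x$drug, r.squared = x$r_squared,
         ic50 = as.numeric(x$ic50), n_points = x$n_points, converged = x$converged)
}

#' @exportS3Method generics::augment
augment.dr_fit <- function(x, data = NULL, ...) {
  pts <- if (is.null(data)) x$data else fit_points(data, if (is.na(x$drug)) NULL else x$drug)
  if (is.null(pts)) abort_validation("No data attached to the fit; pass `data`.")
  pts %>% mutate(.fitted = predict_effect(x, .data$dose),
                 .resid = .data$fa_raw - .data$.fitted)
}

#' @export
predict.dr_fit <- function(object, dose, ...) predict_effect(object, dose)
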