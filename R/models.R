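#' The five dose-response models
#'
#' @description
#' `dr_models()` lists the model identifiers used throughout the package:
#'
#' * `median_effect` — the Chou-Talalay median-effect equation,
#'   `fa = 1 / (1 + (Dm/D)^m)`, derived from the mass-action law. The
#'   effect rises with dose for slope `m > 0`.
#' * `log_logistic_4` — four-parameter log-logistic,
#'   `fa = min + (max - min) / (1 + (D/Dm)^m)`; all of `min`, `max`, `Dm`
#'   and `m` are estimated. The effect rises with dose for `m < 0`.
#' * `log_logistic_min0` — three-parameter variant with the minimum fixed
#'   at 0.
#' * `log_logistic_max1` — three-parameter variant with the maximum fixed
#'   at 1.
#' * `log_logistic_01` — two-parameter variant with asymptotes fixed at
#'   0 and 1; pointwise identical to `median_effect` with the slope sign
#'   flipped (`m_loglogistic = -m_median`).
#'
#' `Dm` is the median-effect dose (the dose at the curve midpoint; for the
#' 0-1 asymptote models the absolute IC50), in molar units.
#'
#' @return Character vector of model names.
#' @export
dr_models <- function() {
  c("median_effect", "log_logistic_4", "log_logistic_min0",
    "log_logistic_max1", "log_logistic_01")
}

model_asymptotes <- function(model, min_asymptote, max_asymptote) {
  switch(model,
    median_effect = c(0, 1),
    log_logistic_01 = c(0, 1),
    log_logistic_min0 = c(0, max_asymptote),
    log_logistic_max1 = c(min_asymptote, 1),
    log_logistic_4 = c(min_asymptote, max_asymptote),
    abort_validation(paste0("Unknown model: ", model)))
}

#' Construct a dose-response fit object directly from parameters
#'
#' Mostly used internally by [fit_model()], but exported so that known
#' true curves (e.g. from a simulation scenario) can be pushed through
#' [predict_effect()], [inverse_dose()] and the combination-index models.
#'
#' @param model One of [dr_models()].
#' @param Dm Median-effect dose (> 0, molar).
#' @param m Slope.
#' @param min_asymptote,max_asymptote Asymptotes; forced to the model's
#'   fixed values where the model demands.
#' @param drug Optional drug label.
#' @param r_squared,ic50,n_points,converged Fit metadata (filled by
#'   [fit_model()]).
#' @param data The (dose, fa) replicate table used for the fit, if any.
#' @return A `dr_fit` object.
#' @export
dr_fit <- function(model, Dm, m, min_asymptote = 0, max_asymptote = 1,
                   drug = NA_character_, r_squared = NA_real_, ic50 = NULL,
                   n_points = NA_integer_, converged = NA, data = NULL) {
  model <- arg_match(model, dr_models())
  if (!is_scalar_number(Dm) || Dm <= 0) abort_validation("`Dm` must be a positive number.")
  if (!is_scalar_number(m) || m == 0) abort_validation("`m` must be a nonzero number.")
  asy <- model_asymptotes(model, min_asymptote, max_asymptote)
  if (asy[1] >= asy[2]) abort_validation("min_asymptote must be below max_asymptote.")
  structure(list(model = model, drug = drug, Dm = Dm, m = m,
                 min_asymptote = asy[1], max_asymptote = asy[2],
                 r_squared = r_squared, ic50 = ic50,
                 n_points = n_points, converged = converged, data = data),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<dr_fit> %s%s\n", x$model,
              if (!is.na(x$drug)) paste0(" [", x$drug, "]") else ""))
  cat(sprintf("  Dm = %.4g M, m = %.4g, asymptotes [%.3g, %.3g]\n",
              x$Dm, x$m, x$min_asymptote, x$max_asymptote))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f", x$r_squared))
  ic <- x$ic50
  if (!is.null(ic)) {
    cat(if (is.na(ic)) "  IC50 = undefined" else sprintf("  IC50 = %.4g M", ic))
  }
  if (!is.na(x$r_squared) || !is.null(ic)) cat("\n")
  invisible(x)
}

#' Predicted fraction affected at a dose
#'
#' Evaluates the fitted curve's closed form. The zero dose is the limiting
#' asymptote and is deliberately outside the domain (callers handle it).
#'
#' @param fit A [dr_fit()] object.
#' @param dose Positive dose(s), molar. Vectorised.
#' @return Fraction affected.
#' @export
#' @examples
#' f <- dr_fit("median_effect", Dm = 1e-8, m = 1)
#' predict_effect(f, 1e-8)  # 0.5 at the median-effect dose
predict_effect <- function(fit, dose) {
  stopifnot(inherits(fit, "dr_fit"))
  if (any(!is.finite(dose) | dose <= 0)) {
    abort_domain("`dose` must be strictly positive (dose 0 is the limiting asymptote).")
  }
  if (fit$model == "median_effect") {
    1 / (1 + (fit$Dm / dose)^fit$m)
  } else {
    fit$min_asymptote +
      (fit$max_asymptote - fit$min_asymptote) / (1 + (dose / fit$Dm)^fit$m)
  }
}

#' Attainable open interval of effects for a fitted curve
#'
#' @param fit A [dr_fit()] object.
#' @return Numeric `c(lower, upper)`; effects strictly inside are invertible.
#' @export
attainable_range <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  c(fit$min_asymptote, fit$max_asymptote)
}

#' Dose producing a given fraction affected (curve inversion)
#'
#' The closed-form inverses of the five models, e.g.
#' `D = Dm * (fa / (1 - fa))^(1/m)` for the median-effect model. Used for
#' IC50 and for the Loewe equivalent doses.
#'
#' @param fit A [dr_fit()] object.
#' @param fa Effect(s) strictly inside [attainable_range()]. Vectorised.
#' @return Dose(s), molar.
#' @export
inverse_dose <- function(fit, fa) {
  stopifnot(inherits(fit, "dr_fit"))
  rng <- attainable_range(fit)
  if (any(!is.finite(fa) | fa <= rng[1] | fa >= rng[2])) {
    abort_range(
      sprintf("`fa` must lie strictly inside the attainable interval (%g, %g).",
              rng[1], rng[2]),
      attainable = rng)
  }
  if (fit$model == "median_effect") {
    fit$Dm * (fa / (1 - fa))^(1 / fit$m)
  } else {
    lo <- fit$min_asymptote; hi <- fit$max_asymptote
    fit$Dm * ((hi - lo) / (fa - lo) - 1)^(1 / fit$m)
  }
}
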