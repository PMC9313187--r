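#' Combination index kernels
#'
#' @description
#' Scalar (vectorised) combination-index formulas comparing the observed
#' combined effect `e_ab` with a non-interaction reference built from the
#' single-drug effects at the same doses. CI < 1 indicates synergy,
#' CI > 1 antagonism, CI = 1 additivity.
#'
#' * `ci_additivity()` — response additivity (linear interaction):
#'   `CI = (E_A + E_B) / E_AB`.
#' * `ci_hsa()` — highest single agent: `CI = max(E_A, E_B) / E_AB`.
#' * `ci_bliss()` — Bliss independence, treating the two effects as
#'   probabilities of independent events:
#'   `CI = (E_A + E_B - E_A * E_B) / E_AB` (requires effects in \[0, 1\]).
#'
#' A non-positive observed effect `e_ab` makes the ratio undefined; these
#' kernels return `NA` there (the grid-level wrapper records the reason).
#'
#' @param e_a,e_b Single-drug fractions affected at the combination's doses.
#' @param e_ab Observed combined fraction affected.
#' @return CI value(s); `NA` where `e_ab <= 0`.
#' @name ci_effect_based
NULL

#' @rdname ci_effect_based
#' @export
ci_additivity <- function(e_a, e_b, e_ab) {
  ifelse(e_ab > 0, (e_a + e_b) / e_ab, NA_real_)
}

#' @rdname ci_effect_based
#' @export
ci_hsa <- function(e_a, e_b, e_ab) {
  ifelse(e_ab > 0, pmax(e_a, e_b) / e_ab, NA_real_)
}

#' @rdname ci_effect_based
#' @export
ci_bliss <- function(e_a, e_b, e_ab) {
  if (any(e_a < 0 | e_a > 1 | e_b < 0 | e_b > 1, na.rm = TRUE)) {
    abort_validation("Bliss independence needs single-drug effects within [0, 1].")
  }
  ifelse(e_ab > 0, (e_a + e_b - e_a * e_b) / e_ab, NA_real_)
}

#' Loewe additivity combination index for one cell
#'
#' `CI = a / A + b / B`, where `A` and `B` are the equivalent doses: the
#' doses at which each drug alone reaches the observed combined effect,
#' obtained by inverting the fitted single-drug curves. In `"lenient"`
#' mode an observed effect outside a curve's attainable range is clamped
#' into the range shrunk by `delta` on each side (flagged); in `"strict"`
#' mode such cells are `NA` with a reason.
#'
#' @param a,b Doses of the two drugs in the combination (> 0).
#' @param e_ab Observed combined fraction affected.
#' @param fit_a,fit_b [dr_fit()] objects for the two drugs; must share the
#'   same dose-response model.
#' @param mode `"lenient"` (default) or `"strict"`.
#' @param delta Range shrink used by the lenient clamp (fa units).
#' @return A list: `ci`, `A`, `B`, `clamped`, `reason`.
#' @export
ci_loewe <- function(a, b, e_ab, fit_a, fit_b, mode = c("lenient", "strict"),
                     delta = 1e-4) {
  mode <- arg_match(mode)
  stopifnot(inherits(fit_a, "dr_fit"), inherits(fit_b, "dr_fit"))
  if (!identical(fit_a$model, fit_b$model)) {
    abort_validation("Loewe CI requires the same dose-response model for both drugs.")
  }
  if (a <= 0 || b <= 0) abort_domain("Combination doses must be positive.")
  miss <- function(reason) list(ci = NA_real_, A = NA_real_, B = NA_real_,
                                clamped = FALSE, reason = reason)
  rng <- c(max(attainable_range(fit_a)[1], attainable_range(fit_b)[1]),
           min(attainable_range(fit_a)[2], attainable_range(fit_b)[2]))
  lo <- rng[1] + delta; hi <- rng[2] - delta
  if (lo >= hi) return(miss("curves have no common attainable effect range"))
  clamped <- FALSE
  e <- e_ab
  if (e <= rng[1] || e >= rng[2]) {
    if (mode == "strict") {
      return(miss(sprintf("observed effect %.4g outside attainable range (%.4g, %.4g)",
                          e_ab, rng[1], rng[2])))
    }
    e <- clamp(e, lo, hi)
    clamped <- TRUE
  }
  A <- unname(inverse_dose(fit_a, e))
  B <- unname(inverse_dose(fit_b, e))
  list(ci = a / A + b / B, A = A, B = B, clamped = clamped, reason = NA_character_)
}

#' Zero interaction potency (ZIP) combination index for one cell
#'
#' Combines the Bliss probabilistic union with curve-predicted single-drug
#' effects: `CI = (EE_A + EE_B - EE_A * EE_B) / E_AB`, where
#' `EE_A = predict_effect(fit_a, a)` and `EE_B = predict_effect(fit_b, b)`
#' are the expected effects from the fitted dose-response curves (clipped
#' to \[0, 1\] so the union stays a probability).
#'
#' @inheritParams ci_loewe
#' @return A list: `ci`, `ee_a`, `ee_b`, `reason`.
#' @export
ci_zip <- function(a, b, e_ab, fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dr_fit"), inherits(fit_b, "dr_fit"))
  if (!identical(fit_a$model, fit_b$model)) {
    abort_validation("ZIP CI requires the same dose-response model for both drugs.")
  }
  if (a <= 0 || b <= 0) abort_domain("Combination doses must be positive.")
  ee_a <- clamp(unname(predict_effect(fit_a, a)), 0, 1)
  ee_b <- clamp(unname(predict_effect(fit_b, b)), 0, 1)
  if (e_ab <= 0) {
    return(list(ci = NA_real_, ee_a = ee_a, ee_b = ee_b,
                reason = "zero combined effect"))
  }
  list(ci = (ee_a + ee_b - ee_a * ee_b) / e_ab, ee_a = ee_a, ee_b = ee_b,
       reason = NA_character_)
}

#' Classify a combination index value
#'
#' The literal rule is synergy if CI < 1, antagonism if CI > 1, additivity
#' at CI = 1; because exact equality is measure-zero on real data an
#' optional half-width `band` widens "additive" to `[1 - band, 1 + band]`.
#' The default `band = 0` keeps the literal rule.
#'
#' @param ci CI value(s), > 0 (NA allowed, classified `"undefined"`).
#' @param band Half-width of the additivity band (>= 0).
#' @return Factor with levels synergistic, additive, antagonistic, undefined.
#' @export
classify_ci <- function(ci, band = 0) {
  if (!is_scalar_number(band) || band < 0) abort_validation("`band` must be >= 0.")
  if (any(!is.na(ci) & ci <= 0)) abort_validation("CI values must be positive.")
  out <- case_when(
    is.na(ci) ~ "undefined",
    ci < 1 - band ~ "synergistic",
    ci > 1 + band ~ "antagonistic",
    TRUE ~ "additive")
  factor(out, levels = c("synergistic", "additive", "antagonistic", "undefined"))
}

#' Combination-index models available
#' @return Character vector of CI model names.
#' @export
ci_models <- function() c("additivity", "hsa", "bliss", "loewe", "zip")

pick_dr_model <- function(fits_a, fits_b) {
  # highest mean R^2 across the two margins, models where both fitted
  merged <- dplyr::inner_join(
    fits_a %>% select(all_of(c("model", "r_squared"))) %>% rename(r2_a = "r_squared"),
    fits_b %>% select(all_of(c("model", "r_squared"))) %>% rename(r2_b = "r_squared"),
    by = "model") %>%
    filter(is.finite(.data$r2_a), is.finite(.data$r2_b)) %>%
    mutate(mean_r2 = (.data$r2_a + .data$r2_b) / 2) %>%
    arrange(dplyr::desc(.data$mean_r2))
  if (nrow(merged) == 0) abort_validation("No dose-response model fits both margins.")
  merged$model[1]
}

#' Compute a combination-index grid over a checkerboard
#'
#' The central analysis step: every interior cell (both doses > 0) of a
#' normalised (and optionally outlier-screened) [combo_grid()] gets a CI
#' under the chosen model, plus a synergy classification. Effect-based
#' models (`additivity`, `hsa`, `bliss`) read the single-drug effects
#' `E_A`, `E_B` straight from the grid margins at the matching doses (no
#' interpolation). Dose-effect-based models (`loewe`, `zip`) first fit
#' one shared dose-response model to both margins; `dr_model = "auto"`
#' picks the model with the best mean R-squared across the two margins.
#'
#' @param grid A normalised [combo_grid()].
#' @param ci_model One of [ci_models()].
#' @param dr_model One of [dr_models()], or `"auto"`; used by loewe/zip.
#' @param mode Loewe out-of-range handling, `"lenient"` or `"strict"`.
#' @param band Additivity classification half-width (see [classify_ci()]).
#' @return A `ci_grid` tibble: one row per interior cell with `dose_a`,
#'   `dose_b`, `e_a`, `e_b`, `e_ab`, `ci`, `classification`, `reason`,
#'   plus `equiv_a`, `equiv_b`, `clamped` (loewe) or `ee_a`, `ee_b` (zip).
#'   Attributes carry the CI model, the dose-response model used and the
#'   margin fits.
#' @export
compute_ci_grid <- function(grid, ci_model = c("loewe", "additivity", "hsa",
                                               "bliss", "zip"),
                            dr_model = "auto", mode = c("lenient", "strict"),
                            band = 0) {
  ci_model <- arg_match(ci_model, ci_models())
  mode <- arg_match(mode)
  stopifnot(inherits(grid, "combo_grid"))
  eff <- grid_effects(grid)
  margin_a <- eff %>% filter(.data$dose_b == 0, .data$dose_a > 0) %>%
    select(dose = "dose_a", e = "effect")
  margin_b <- eff %>% filter(.data$dose_a == 0, .data$dose_b > 0) %>%
    select(dose = "dose_b", e = "effect")
  interior <- eff %>% filter(.data$dose_a > 0, .data$dose_b > 0) %>%
    left_join(margin_a %>% rename(e_a = "e"), by = c(dose_a = "dose")) %>%
    left_join(margin_b %>% rename(e_b = "e"), by = c(dose_b = "dose")) %>%
    rename(e_ab = "effect")

  fits <- NULL; used_dr_model <- NA_character_
  if (ci_model %in% c("loewe", "zip")) {
    da <- grid_margin(grid, "a"); db <- grid_margin(grid, "b")
    if (identical(dr_model, "auto")) {
      all_a <- fit_all_models(da); all_b <- fit_all_models(db)
      used_dr_model <- pick_dr_model(all_a, all_b)
    } else {
      used_dr_model <- arg_match(dr_model, dr_models())
    }
    fit_a <- tryCatch(fit_model(da, used_dr_model), error = function(e) {
      abort_validation(paste0("Margin fit failed for drug ", attr(grid, "drug_a"),
                              ": ", conditionMessage(e)))
    })
    fit_b <- tryCatch(fit_model(db, used_dr_model), error = function(e) {
      abort_validation(paste0("Margin fit failed for drug ", attr(grid, "drug_b"),
                              ": ", conditionMessage(e)))
    })
    fits <- list(a = fit_a, b = fit_b)
  }

  res <- interior
  if (ci_model == "additivity") {
    res$ci <- ci_additivity(res$e_a, res$e_b, res$e_ab)
    res$reason <- ifelse(is.na(res$ci), "zero combined effect", NA_character_)
  } else if (ci_model == "hsa") {
    res$ci <- ci_hsa(res$e_a, res$e_b, res$e_ab)
    res$reason <- ifelse(is.na(res$ci), "zero combined effect", NA_character_)
  } else if (ci_model == "bliss") {
    res$ci <- ci_bliss(res$e_a, res$e_b, res$e_ab)
    res$reason <- ifelse(is.na(res$ci), "zero combined effect", NA_character_)
  } else if (ci_model == "loewe") {
    cells <- purrr::pmap(list(res$dose_a, res$dose_b, res$e_ab), function(a, b, e) {
      ci_loewe(a, b, e, fits$a, fits$b, mode = mode)
    })
    res$ci <- purrr::map_dbl(cells, "ci")
    res$equiv_a <- purrr::map_dbl(cells, "A")
    res$equiv_b <- purrr::map_dbl(cells, "B")
    res$clamped <- purrr::map_lgl(cells, "clamped")
    res$reason <- purrr::map_chr(cells, "reason")
  } else {
    cells <- purrr::pmap(list(res$dose_a, res$dose_b, res$e_ab), function(a, b, e) {
      ci_zip(a, b, e, fits$a, fits$b)
    })
    res$ci <- purrr::map_dbl(cells, "ci")
    res$ee_a <- purrr::map_dbl(cells, "ee_a")
    res$ee_b <- purrr::map_dbl(cells, "ee_b")
    res$reason <- purrr::map_chr(cells, "reason")
  }
  res$classification <- classify_ci(res$ci, band)
  res <- res %>% select(all_of(c("dose_a", "dose_b", "e_a", "e_b", "e_ab",
                                 "n_replicates", "ci", "classification", "reason")),
                        dplyr::any_of(c("equiv_a", "equiv_b", "clamped", "ee_a", "ee_b")))
  structure(res,
            class = c("ci_grid", class(as_tibble(res))),
            ci_model = ci_model, dr_model = used_dr_model,
            mode = mode, band = band, fits = fits,
            drug_a = attr(grid, "drug_a"), drug_b = attr(grid, "drug_b"))
}

#' @export
print.ci_grid <- function(x, ...) {
  cat(sprintf("# ci_grid: %s model (%s x %s)%s, %d interior cells\n",
              attr(x, "ci_model"), attr(x, "drug_a"), attr(x, "drug_b"),
              if (!is.na(attr(x, "dr_model"))) paste0(", curves: ", attr(x, "dr_model")) else "",
              nrow(x)))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.ci_grid <- function(x, ...) {
  tibble(ci_model = attr(x, "ci_model"), dr_model = attr(x, "dr_model"),
         n_cells = nrow(x), n_defined = sum(!is.na(x$ci)),
         median_ci = median(x$ci, na.rm = TRUE),
         n_synergistic = sum(x$classification == "synergistic"),
         n_additive = sum(x$classification == "additive"),
         n_antagonistic = sum(x$classification == "antagonistic"))
}
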