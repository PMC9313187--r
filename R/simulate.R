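#' True dose-response curve parameters for a simulated drug
#'
#' @param name Drug label.
#' @param model One of [dr_models()].
#' @param Dm Median-effect dose (molar).
#' @param m Slope (log-logistic convention for the log-logistic models:
#'   effect rises with dose for `m < 0`).
#' @param min_asymptote,max_asymptote Curve asymptotes.
#' @return A list of class `drug_params`; also a valid [dr_fit()] carrier
#'   via `as_dr_fit()`.
#' @export
drug_params <- function(name = "drug_A", model = "log_logistic_01",
                        Dm = 1e-8, m = -1, min_asymptote = 0, max_asymptote = 1) {
  fit <- dr_fit(model, Dm = Dm, m = m, min_asymptote = min_asymptote,
                max_asymptote = max_asymptote, drug = name)
  structure(list(name = name, model = model, Dm = Dm, m = m,
                 min_asymptote = fit$min_asymptote,
                 max_asymptote = fit$max_asymptote),
            class = "drug_params")
}

#' Convert true drug parameters to a `dr_fit` carrier
#' @param params A [drug_params()] object.
#' @return A [dr_fit()] holding the true curve.
#' @export
as_dr_fit <- function(params) {
  stopifnot(inherits(params, "drug_params"))
  dr_fit(params$model, Dm = params$Dm, m = params$m,
         min_asymptote = params$min_asymptote, max_asymptote = params$max_asymptote,
         drug = params$name, converged = TRUE)
}

#' Define a simulation scenario for synthetic plates
#'
#' Describes a CyQUANT-style plate experiment with known ground truth:
#' dose design, replicate count, Gaussian plate noise and optional
#' injected outliers, plus the interaction rule for checkerboard grids.
#' Defaults mirror a typical validation design: 7 nonzero doses at
#' half-log spacing centred on the drug's own median-effect dose,
#' triplicate wells, and fa-scale noise of 0.02.
#'
#' @param drug_a,drug_b [drug_params()] for the drug(s); `drug_b` only
#'   needed for combination grids.
#' @param n_doses Nonzero doses per drug.
#' @param dose_factor Ratio between consecutive doses (default half-log,
#'   `sqrt(10)`).
#' @param replicates Wells per dose (or per grid cell).
#' @param noise_sd Gaussian noise SD on the fa scale (applied to the raw
#'   signal as `noise_sd * reference_signal`).
#' @param reference_signal Mean untreated-well signal.
#' @param outlier_n Number of contaminated wells (0 = clean plate).
#' @param outlier_sd Outlier magnitude in units of `noise_sd`.
#' @param outlier_doses Optional dose indices (1 = lowest nonzero dose)
#'   eligible for contamination; default all nonzero doses.
#' @param interaction Interaction rule for grids:
#'   `"bliss_independent"` (effects combine as independent probabilities),
#'   `"loewe_additive_sham"` (exact dose addition; requires shared curve
#'   shape), `"synergy_kappa"` / `"antagonism_kappa"` (Loewe surface with
#'   drug B's dose scaled by `kappa`; `kappa > 1` synergy, `< 1`
#'   antagonism).
#' @param kappa Potency-shift factor (> 0) for the kappa rules.
#' @param seed Integer seed; every simulation from the scenario is
#'   reproducible.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(drug_a = drug_params("drug_A"),
                                drug_b = NULL,
                                n_doses = 7, dose_factor = sqrt(10),
                                replicates = 3, noise_sd = 0.02,
                                reference_signal = 1000,
                                outlier_n = 0, outlier_sd = 10,
                                outlier_doses = NULL,
                                interaction = c("bliss_independent",
                                                "loewe_additive_sham",
                                                "synergy_kappa",
                                                "antagonism_kappa"),
                                kappa = 1, seed = 1L) {
  interaction <- arg_match(interaction)
  stopifnot(inherits(drug_a, "drug_params"))
  if (!is.null(drug_b)) stopifnot(inherits(drug_b, "drug_params"))
  if (!is_scalar_number(kappa) || kappa <= 0) abort_validation("`kappa` must be > 0.")
  if (interaction %in% c("synergy_kappa", "antagonism_kappa") && missing(kappa)) {
    abort_schema(paste0("`kappa` must be given explicitly for interaction = \"",
                        interaction, "\"."))
  }
  if (replicates < 1 || noise_sd < 0 || n_doses < 1) {
    abort_validation("Need replicates >= 1, noise_sd >= 0, n_doses >= 1.")
  }
  structure(list(drug_a = drug_a, drug_b = drug_b, n_doses = n_doses,
                 dose_factor = dose_factor, replicates = replicates,
                 noise_sd = noise_sd, reference_signal = reference_signal,
                 outlier_n = outlier_n, outlier_sd = outlier_sd,
                 outlier_doses = outlier_doses,
                 interaction = interaction, kappa = kappa,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

# IC50-centred log-spaced dose series: the middle dose sits at Dm.
scenario_doses <- function(params, n_doses, dose_factor) {
  mid <- (n_doses + 1) / 2
  params$Dm * dose_factor^(seq_len(n_doses) - mid)
}

true_effect <- function(params, dose) {
  fit <- as_dr_fit(params)
  out <- numeric(length(dose))
  pos <- dose > 0
  out[pos] <- predict_effect(fit, dose[pos])
  # the zero dose sits at the no-effect asymptote
  lo_end <- if (params$model == "median_effect") {
    if (params$m > 0) 0 else 1
  } else {
    if (params$m < 0) params$min_asymptote else params$max_asymptote
  }
  out[!pos] <- lo_end
  out
}

signal_from_fa <- function(fa_true, scenario, n) {
  ref <- scenario$reference_signal
  ref * (1 - fa_true) + rnorm(n, 0, scenario$noise_sd * ref)
}

inject_outliers <- function(tbl, scenario) {
  if (scenario$outlier_n == 0) return(tbl)
  nz <- sort(unique(tbl$dose[tbl$dose > 0]))
  eligible_doses <- if (is.null(scenario$outlier_doses)) nz else nz[scenario$outlier_doses]
  pool <- which(tbl$dose %in% eligible_doses)
  if (scenario$outlier_n > length(pool)) {
    abort_validation("More outliers requested than eligible wells.")
  }
  hit <- sample(pool, scenario$outlier_n)
  # lower signal -> higher apparent fraction affected
  shift <- scenario$outlier_sd * scenario$noise_sd * scenario$reference_signal
  tbl$response[hit] <- tbl$response[hit] - shift
  tbl$outlier <- FALSE
  tbl$outlier[hit] <- TRUE
  tbl
}

#' Simulate a single-drug plate
#'
#' Generates raw-signal wells: `signal = reference * (1 - fa_true(D)) +
#' N(0, noise_sd * reference)`, with dose-0 wells at the reference level,
#' over an IC50-centred log-spaced dose series. Outliers (if requested)
#' lower the signal of seeded wells by `outlier_sd` noise units, i.e.
#' raise their apparent effect. Fully reproducible from the scenario seed.
#'
#' @param scenario A [simulation_scenario()].
#' @param which `"a"` or `"b"`: which drug of the scenario to simulate.
#' @return A raw [dr_data()] tibble (with an `outlier` truth column when
#'   contamination was requested).
#' @export
simulate_single_drug <- function(scenario, which = c("a", "b")) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  which <- arg_match(which)
  params <- if (which == "a") scenario$drug_a else scenario$drug_b
  if (is.null(params)) abort_validation("The scenario has no drug_b.")
  withr_seed <- scenario$seed + if (which == "a") 0L else 1L
  set.seed(withr_seed)
  doses <- c(0, scenario_doses(params, scenario$n_doses, scenario$dose_factor))
  tbl <- tidyr::expand_grid(dose = doses, replicate = seq_len(scenario$replicates))
  fa_true <- true_effect(params, tbl$dose)
  tbl <- tbl %>% mutate(drug = params$name,
                        response = signal_from_fa(fa_true, scenario, dplyr::n()))
  tbl <- inject_outliers(tbl, scenario)
  out <- dr_data(tbl)
  if ("outlier" %in% names(tbl)) {
    key <- tbl %>% arrange(.data$drug, .data$dose) %>%
      group_by(.data$drug, .data$dose) %>% mutate(replicate = row_number()) %>% ungroup()
    out$outlier <- key$outlier
  }
  out
}

true_grid_effect <- function(scenario, a, b) {
  pa <- scenario$drug_a; pb <- scenario$drug_b
  fa_a <- true_effect(pa, a)
  fa_b <- true_effect(pb, b)
  same_shape <- identical(pa$model, pb$model) && pa$m == pb$m &&
    pa$min_asymptote == pb$min_asymptote && pa$max_asymptote == pb$max_asymptote
  if (scenario$interaction == "bliss_independent") {
    return(ifelse(a == 0, fa_b, ifelse(b == 0, fa_a, fa_a + fa_b - fa_a * fa_b)))
  }
  # dose-addition surfaces need a common shape so that drug B is an exact
  # potency-scaled copy of drug A
  if (!same_shape) {
    abort_validation("Dose-addition interaction rules need both drugs to share the curve shape (model, m, asymptotes).")
  }
  pot <- pa$Dm / pb$Dm  # dose b of B acts like pot*b of A
  kap <- switch(scenario$interaction,
                loewe_additive_sham = 1,
                synergy_kappa = scenario$kappa,
                antagonism_kappa = scenario$kappa)
  eq_dose <- a + pot * kap * b
  ifelse(a == 0 & b == 0, true_effect(pa, 0),
         ifelse(a == 0, fa_b, ifelse(b == 0, fa_a, true_effect(pa, eq_dose))))
}

#' Simulate a two-drug checkerboard plate
#'
#' Builds the full dose matrix (zero margins included) with interior true
#' effects set by the scenario's interaction rule, margins from the
#' single-drug curves, and plate noise as in [simulate_single_drug()].
#' The Bliss rule combines the margin effects as independent
#' probabilities; the dose-addition rules evaluate drug A's curve at the
#' combined A-equivalent dose `a + pot * kappa * b` (with `pot` the
#' potency ratio `Dm_A / Dm_B`), which is exactly Loewe-additive for
#' `kappa = 1`, synergistic for `kappa > 1` and antagonistic for
#' `kappa < 1`.
#'
#' @param scenario A [simulation_scenario()] with both drugs set.
#' @return A raw [combo_grid()] tibble.
#' @export
simulate_combination <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (is.null(scenario$drug_b)) abort_validation("Combination scenarios need `drug_b`.")
  set.seed(scenario$seed + 2L)
  doses_a <- c(0, scenario_doses(scenario$drug_a, scenario$n_doses, scenario$dose_factor))
  doses_b <- c(0, scenario_doses(scenario$drug_b, scenario$n_doses, scenario$dose_factor))
  tbl <- tidyr::expand_grid(dose_a = doses_a, dose_b = doses_b,
                            replicate = seq_len(scenario$replicates))
  fa_true <- true_grid_effect(scenario, tbl$dose_a, tbl$dose_b)
  tbl <- tbl %>% mutate(response = signal_from_fa(fa_true, scenario, dplyr::n()))
  combo_grid(tbl, drug_a = scenario$drug_a$name, drug_b = scenario$drug_b$name)
}

#' True combination-index surface of a scenario
#'
#' The noise-free CI each model's own null would assign, computed from the
#' scenario's true curves and interaction rule — the ground truth a
#' recovered [compute_ci_grid()] should approach.
#'
#' @param scenario A [simulation_scenario()] with both drugs set.
#' @param ci_model One of [ci_models()].
#' @return Tibble `dose_a`, `dose_b`, `e_a`, `e_b`, `e_ab`, `ci`.
#' @export
true_ci_surface <- function(scenario, ci_model = c("loewe", "additivity", "hsa",
                                                   "bliss", "zip")) {
  ci_model <- arg_match(ci_model, ci_models())
  if (is.null(scenario$drug_b)) abort_validation("Combination scenarios need `drug_b`.")
  doses_a <- scenario_doses(scenario$drug_a, scenario$n_doses, scenario$dose_factor)
  doses_b <- scenario_doses(scenario$drug_b, scenario$n_doses, scenario$dose_factor)
  cells <- tidyr::expand_grid(dose_a = doses_a, dose_b = doses_b) %>%
    mutate(e_a = true_effect(scenario$drug_a, .data$dose_a),
           e_b = true_effect(scenario$drug_b, .data$dose_b),
           e_ab = true_grid_effect(scenario, .data$dose_a, .data$dose_b))
  fa <- as_dr_fit(scenario$drug_a); fb <- as_dr_fit(scenario$drug_b)
  cells$ci <- switch(ci_model,
    additivity = ci_additivity(cells$e_a, cells$e_b, cells$e_ab),
    hsa = ci_hsa(cells$e_a, cells$e_b, cells$e_ab),
    bliss = ci_bliss(cells$e_a, cells$e_b, cells$e_ab),
    loewe = purrr::pmap_dbl(list(cells$dose_a, cells$dose_b, cells$e_ab),
                            function(a, b, e) ci_loewe(a, b, e, fa, fb)$ci),
    zip = purrr::pmap_dbl(list(cells$dose_a, cells$dose_b, cells$e_ab),
                          function(a, b, e) ci_zip(a, b, e, fa, fb)$ci))
  cells
}
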