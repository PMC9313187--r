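# Shared fixtures built in code.

# A clean long-format plate table: one drug, 7 half-log doses + control,
# noiseless signals from a 0-1 log-logistic curve.
clean_plate <- function(drug = "X", Dm = 1e-8, m = -1, reps = 3, ref = 1000) {
  doses <- c(0, Dm * sqrt(10)^(-3:3))
  fit <- dr_fit("log_logistic_01", Dm = Dm, m = m)
  fa <- c(0, predict_effect(fit, doses[-1]))
  tidyr::expand_grid(dose = doses, replicate = seq_len(reps)) |>
    dplyr::mutate(drug = drug,
                  response = ref * (1 - fa[match(dose, doses)]))
}

normalized_plate <- function(...) {
  normalize_responses(dr_data(clean_plate(...)), "zero_dose")
}

# Random valid parameter sets per model, for property-style loops.
random_fit <- function(model) {
  Dm <- 10^stats::runif(1, -9, -5)
  m <- sample(c(-1, 1), 1) * stats::runif(1, 0.4, 4)
  lo <- stats::runif(1, 0, 0.3)
  hi <- stats::runif(1, 0.7, 1)
  switch(model,
    median_effect = dr_fit(model, Dm, m),
    log_logistic_01 = dr_fit(model, Dm, m),
    log_logistic_min0 = dr_fit(model, Dm, m, max_asymptote = hi),
    log_logistic_max1 = dr_fit(model, Dm, m, min_asymptote = lo),
    log_logistic_4 = dr_fit(model, Dm, m, min_asymptote = lo, max_asymptote = hi))
}
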