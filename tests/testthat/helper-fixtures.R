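# shared fixtures: a compact parameter set with one covariate, a direct
# bundle simulator, and a small hand-checkable record table

tiny_params <- function(beta_f = -0.3, tau2 = 0.08, gamma_x = -0.01) {
  model_parameters(
    beta0 = 5.2, beta_x = 0.003, beta_f = beta_f, beta_c = c(age = 0.002),
    sigma2 = 0.03,
    gamma0 = 3.7, gamma_x = gamma_x, gamma_c = c(age = 0.001),
    omega2 = 0.04, tau2 = tau2
  )
}

# simulate observables straight from the generative model (no CSV layer)
sim_bundle <- function(params, n, seed, keep_truth = FALSE) {
  set.seed(seed)
  x <- rlnorm(n, log(2), 0.5)
  cm <- cbind(age = rnorm(n, 0, 15))
  lat <- simulate_latent(params, x, cm)
  b <- design_bundle(lat$y, x, lat$f_star_1, lat$f_star_2, cm)
  if (keep_truth) list(bundle = b, f = lat$f, x = x, cmat = cm) else b
}

# n-row record table with deterministic, hand-checkable values
fixture_records <- function(n = 10) {
  set.seed(20)
  df <- data.frame(
    subject_id = seq_len(n),
    pfoa = round(runif(n, 0.5, 6), 2),
    pfos = round(runif(n, 2, 20), 2),
    pfna = round(runif(n, 0.2, 2), 2),
    cholesterol = round(runif(n, 140, 240), 1),
    energy_d1 = round(runif(n, 1200, 3200)),
    energy_d2 = round(runif(n, 1200, 3200)),
    total_fiber_d1 = round(runif(n, 5, 30), 1),
    total_fiber_d2 = round(runif(n, 5, 30), 1),
    soluble_fiber_d1 = round(runif(n, 2, 10), 1),
    soluble_fiber_d2 = round(runif(n, 2, 10), 1),
    age = sample(20:79, n, replace = TRUE),
    sex = rep_len(c("female", "male"), n),
    race_ethnicity = rep_len(c("nh_white", "nh_black", "mexican_american",
                               "other_hispanic", "other_multi"), n),
    income_poverty_ratio = round(runif(n, 0.5, 5), 2),
    smoking = rep_len(0:3, n),
    wave = rep_len(1:7, n),
    sat_fat = round(runif(n, 10, 40), 1),
    diet_cholesterol = round(runif(n, 100, 450), 1),
    on_chol_medication = FALSE,
    stringsAsFactors = FALSE
  )
  subject_records(df)
}
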