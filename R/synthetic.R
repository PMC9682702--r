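# forward simulator of the full generative structure: right-skewed PFAS
# exposures, NHANES-like covariates, latent fiber, log-linear cholesterol,
# and two conditionally independent recall replicates — plus the classical
# attenuation algebra used across the test harnesses

#' Default generating parameters for synthetic studies
#'
#' Values chosen so a synthetic study resembles the serum-cholesterol /
#' serum-PFAS setting the package targets: a PFAS coefficient near
#' 2.4e-3 per ng/mL on ln(cholesterol), a soluble-fiber coefficient of
#' -0.03 per ln-unit, an inverse fiber-PFAS association, residual SD of
#' ln(cholesterol) of 0.17, and replicate measurement error giving the
#' two-day mean a reliability of 0.8. Illustrative defaults, not estimates;
#' see the methods vignette for the reasoning behind each value.
#'
#' @param marginals A [default_marginals()] list (used for the covariate
#'   coefficient names).
#' @return A [model_parameters()] object.
#' @export
default_parameters <- function(marginals = default_marginals()) {
  cn <- covariate_names(marginals)
  beta_c <- stats::setNames(numeric(length(cn)), cn)
  gamma_c <- beta_c
  # modest covariate effects on ln(cholesterol)
  beta_c[c("energy", "sat_fat", "diet_cholesterol", "age",
           "income_poverty_ratio", "smoking", "wave", "wave2")] <-
    c(-5e-6, 4e-4, 5e-5, 1.5e-3, 5e-3, 1e-2, -2e-3, 5e-4)
  beta_c[grep("^sex_", cn)] <- 0.04
  beta_c[grep("^race_", cn)] <- c(-0.01, 0.01, -0.02, 0.02)
  # modest covariate effects on latent fiber (ln scale)
  gamma_c[c("energy", "sat_fat", "diet_cholesterol", "age",
            "income_poverty_ratio", "smoking", "wave", "wave2")] <-
    c(0, -1e-3, -5e-5, 1e-3, 5e-3, -1e-2, 1e-3, 0)
  gamma_c[grep("^sex_", cn)] <- -0.02
  gamma_c[grep("^race_", cn)] <- c(0.01, -0.01, 0.015, -0.005)
  model_parameters(
    beta0 = 5.25, beta_x = 2.42e-3, beta_f = -0.03, beta_c = beta_c,
    sigma2 = 0.0289,
    gamma0 = log(40), gamma_x = -0.006, gamma_c = gamma_c,
    omega2 = 0.007, tau2 = 0.0035
  )
}

#' Default covariate and exposure marginal distributions
#'
#' The sampling laws used by [generate_synthetic()] to emulate an adult
#' NHANES-like analytic sample: log-normal serum PFAS, truncated-normal
#' age, categorical sex/race/smoking, log-normal intakes, and a uniform
#' survey-cycle index over seven waves.
#'
#' @return A named list of marginal specifications.
#' @export
default_marginals <- function() {
  list(
    pfoa = list(meanlog = log(2.2), sdlog = 0.55),
    pfos = list(meanlog = log(8.0), sdlog = 0.75),
    pfna = list(meanlog = log(0.9), sdlog = 0.60),
    energy = list(meanlog = log(2000), sdlog = 0.35),
    age = list(mean = 47, sd = 17, min = 20, max = 85),
    sex = list(levels = c("female", "male"), probs = c(0.52, 0.48)),
    race_ethnicity = list(
      levels = c("nh_white", "nh_black", "mexican_american",
                 "other_hispanic", "other_multi"),
      probs = c(0.40, 0.22, 0.18, 0.10, 0.10)
    ),
    smoking = list(levels = 0:3, probs = c(0.52, 0.23, 0.10, 0.15)),
    income_poverty_ratio = list(meanlog = log(2.0), sdlog = 0.55, max = 5),
    sat_fat = list(meanlog = log(24), sdlog = 0.45),
    diet_cholesterol = list(meanlog = log(250), sdlog = 0.55),
    wave = list(levels = 1:7),
    # raw-scale reconstruction of recall days: fiber = a + b * energy + resid
    fiber_energy = list(
      soluble = list(a = 4, b = 0.0025),
      total = list(a = 8, b = 0.005)
    ),
    # schema filler linking the two fiber columns (total ~ ratio * soluble)
    total_soluble_ratio = 2.8
  )
}

# covariate column names produced by encode_covariates() under the
# generator's fixed reference levels (first level of each category)
covariate_names <- function(marginals = default_marginals()) {
  c("energy", "sat_fat", "diet_cholesterol", "age", "income_poverty_ratio",
    paste0("sex_", marginals$sex$levels[-1L]),
    paste0("race_", sort(marginals$race_ethnicity$levels)[
      sort(marginals$race_ethnicity$levels) != marginals$race_ethnicity$levels[1L]]),
    "smoking", "wave", "wave2")
}

#' Draw latent fiber, outcome, and replicates given exposures
#'
#' The core forward step of the generative model: given exposure `x` and
#' encoded covariates, draws latent fiber from its Gaussian regression,
#' the ln-cholesterol outcome from the outcome regression, and two
#' conditionally independent replicates with classical (nondifferential,
#' unbiased) measurement error.
#'
#' @param params A [model_parameters()]; covariate names must match
#'   `colnames(cmat)`.
#' @param x Numeric exposure vector (ng/mL).
#' @param cmat Encoded covariate matrix (may have zero columns).
#' @return A list of numeric vectors `f`, `y`, `f_star_1`, `f_star_2`.
#'   Uses the current RNG state; callers control the seed.
#' @export
simulate_latent <- function(params, x, cmat = matrix(numeric(0), length(x), 0)) {
  stopifnot(inherits(params, "model_parameters"))
  n <- length(x)
  cmat <- as.matrix(cmat)
  cn <- names(params$beta_c)
  if (length(cn)) {
    if (!all(cn %in% colnames(cmat))) {
      stop("covariate matrix lacks column(s): ",
           paste(setdiff(cn, colnames(cmat)), collapse = ", "), call. = FALSE)
    }
    cmat <- cmat[, cn, drop = FALSE]
  }
  mu_f <- params$gamma0 + params$gamma_x * x +
    if (length(cn)) drop(cmat %*% params$gamma_c) else 0
  f <- mu_f + stats::rnorm(n, 0, sqrt(params$omega2))
  mu_y <- params$beta0 + params$beta_x * x + params$beta_f * f +
    if (length(cn)) drop(cmat %*% params$beta_c) else 0
  y <- mu_y + stats::rnorm(n, 0, sqrt(params$sigma2))
  tau <- sqrt(params$tau2)
  list(f = f, y = y,
       f_star_1 = f + stats::rnorm(n, 0, tau),
       f_star_2 = f + stats::rnorm(n, 0, tau))
}

#' Generate a complete synthetic study
#'
#' Runs the generative model forward at size `n`: draws exposures and
#' covariates from `marginals`, encodes the covariates exactly as the
#' analysis pipeline does (reference level = first declared level of each
#' category), draws latent fiber, outcome, and replicates with
#' [simulate_latent()], and back-transforms everything to the analytic
#' CSV schema — cholesterol in mg/dL and two raw-scale recall days
#' reconstructed by inverting the shift-log and energy-adjustment
#' transforms with the fixed coefficients in
#' `marginals$fiber_energy`. Raw fiber intakes are floored at zero (the
#' inverse transform can produce a slightly negative intake for extreme
#' draws; under the default scales this touches well under 1% of rows).
#'
#' @param n Number of subjects (>= 1).
#' @param params Generating [model_parameters()].
#' @param marginals Marginal distributions, see [default_marginals()].
#' @param fiber_type Which fiber variable carries the latent structure:
#'   `"soluble"` (default) or `"total"`. The other fiber column is filled
#'   by a noisy proportional link so the schema stays complete.
#' @param pfas_analyte Which analyte is the exposure `X` of the model;
#'   the other two are drawn independently.
#' @param seed Integer seed; regenerating with identical arguments
#'   reproduces the dataset exactly.
#' @param shift Shift (g/d) used when inverting the log transform;
#'   default 40.
#' @return An object of class `synthetic_dataset`: `records` (a
#'   [subject_records()] data.frame in the analytic schema), `f_true`
#'   (latent fiber, ln scale), `f_star` (n x 2 matrix of the exact
#'   transformed replicates), `y` (ln cholesterol), `cmat` (the encoded
#'   covariates used), `params`, `fiber_type`, `pfas_analyte`, `seed`.
#'   `f_true` never appears in the exported CSV.
#' @export
generate_synthetic <- function(n, params = default_parameters(),
                               marginals = default_marginals(),
                               fiber_type = c("soluble", "total"),
                               pfas_analyte = c("PFOA", "PFOS", "PFNA"),
                               seed = 1L, shift = 40) {
  stopifnot(n >= 1)
  fiber_type <- match.arg(fiber_type)
  pfas_analyte <- match.arg(pfas_analyte)
  for (nm in c("pfoa", "pfos", "pfna", "energy", "age", "sex",
               "race_ethnicity", "smoking", "income_poverty_ratio",
               "sat_fat", "diet_cholesterol", "wave", "fiber_energy")) {
    if (is.null(marginals[[nm]])) {
      stop("configuration error: marginal spec lacks '", nm, "'",
           call. = FALSE)
    }
  }
  set.seed(seed)
  rlnorm_spec <- function(spec, n) stats::rlnorm(n, spec$meanlog, spec$sdlog)
  draw_cat <- function(spec, n) {
    spec$levels[sample.int(length(spec$levels), n, replace = TRUE,
                           prob = spec$probs)]
  }
  age <- pmin(pmax(stats::rnorm(n, marginals$age$mean, marginals$age$sd),
                   marginals$age$min), marginals$age$max)
  ipr <- pmin(rlnorm_spec(marginals$income_poverty_ratio, n),
              marginals$income_poverty_ratio$max)
  df <- data.frame(
    subject_id = seq_len(n),
    pfoa = rlnorm_spec(marginals$pfoa, n),
    pfos = rlnorm_spec(marginals$pfos, n),
    pfna = rlnorm_spec(marginals$pfna, n),
    energy_d1 = rlnorm_spec(marginals$energy, n),
    energy_d2 = rlnorm_spec(marginals$energy, n),
    age = age,
    sex = draw_cat(marginals$sex, n),
    race_ethnicity = draw_cat(marginals$race_ethnicity, n),
    smoking = as.integer(draw_cat(marginals$smoking, n)),
    income_poverty_ratio = ipr,
    sat_fat = rlnorm_spec(marginals$sat_fat, n),
    diet_cholesterol = rlnorm_spec(marginals$diet_cholesterol, n),
    wave = as.integer(sample(marginals$wave$levels, n, replace = TRUE)),
    on_chol_medication = FALSE,
    stringsAsFactors = FALSE
  )
  cmat <- encode_covariates(
    df,
    reference_levels = list(sex = marginals$sex$levels[1L],
                            race_ethnicity = marginals$race_ethnicity$levels[1L])
  )
  x <- df[[tolower(pfas_analyte)]]
  lat <- simulate_latent(params, x, cmat)

  # invert the analysis transforms to raw-scale recall days:
  # residual_j = exp(F*_j) - shift; fiber_j = a + b * energy_j + residual_j
  fe <- marginals$fiber_energy[[fiber_type]]
  fib1 <- pmax(fe$a + fe$b * df$energy_d1 + exp(lat$f_star_1) - shift, 0)
  fib2 <- pmax(fe$a + fe$b * df$energy_d2 + exp(lat$f_star_2) - shift, 0)
  ratio <- marginals$total_soluble_ratio
  link_noise <- function() stats::rlnorm(n, 0, 0.15)
  if (fiber_type == "soluble") {
    df$soluble_fiber_d1 <- fib1
    df$soluble_fiber_d2 <- fib2
    df$total_fiber_d1 <- fib1 * ratio * link_noise()
    df$total_fiber_d2 <- fib2 * ratio * link_noise()
  } else {
    df$total_fiber_d1 <- fib1
    df$total_fiber_d2 <- fib2
    df$soluble_fiber_d1 <- fib1 / ratio * link_noise()
    df$soluble_fiber_d2 <- fib2 / ratio * link_noise()
  }
  df$cholesterol <- exp(lat$y)
  structure(
    list(records = subject_records(df), f_true = lat$f,
         f_star = cbind(lat$f_star_1, lat$f_star_2), y = lat$y,
         cmat = cmat, params = params, fiber_type = fiber_type,
         pfas_analyte = pfas_analyte, seed = as.integer(seed),
         shift = shift),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: n = %d, latent %s fiber, exposure %s, seed %d\n",
    nrow(x$records), x$fiber_type, x$pfas_analyte, x$seed))
  invisible(x)
}

#' Reliability (attenuation) ratio of a replicate mean
#'
#' Under classical measurement error, regressing on the mean of `k`
#' replicates instead of the true variable shrinks the slope by
#' `lambda = omega2 / (omega2 + tau2 / k)`, the reliability of the
#' k-replicate mean.
#'
#' @param omega2 Between-person (true-score) variance, > 0.
#' @param tau2 Within-person replicate error variance, >= 0.
#' @param k Number of replicates averaged, >= 1.
#' @return `lambda` in (0, 1].
#' @export
#' @examples
#' attenuation_factor(1, 1, 2) # 2/3
attenuation_factor <- function(omega2, tau2, k = 2) {
  if (!is.numeric(omega2) || any(omega2 <= 0)) {
    stop("parameter error: `omega2` must be > 0", call. = FALSE)
  }
  if (!is.numeric(tau2) || any(tau2 < 0)) {
    stop("parameter error: `tau2` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(k) || any(k < 1)) {
    stop("parameter error: `k` must be >= 1", call. = FALSE)
  }
  omega2 / (omega2 + tau2 / k)
}

#' Expected large-sample coefficients of the naive regression
#'
#' Closed-form limits of the OLS coefficients when the k-replicate mean
#' stands in for latent fiber: the fiber slope attenuates to
#' `lambda * beta_f`, and the PFAS slope picks up the residual confounding
#' `beta_x + gamma_x * beta_f * (1 - lambda)`.
#'
#' @param params A [model_parameters()].
#' @param k Number of replicates averaged, default 2.
#' @return A list: `fiber_slope`, `pfas_slope`, `lambda`.
#' @export
expected_naive_bias <- function(params, k = 2) {
  stopifnot(inherits(params, "model_parameters"))
  lam <- attenuation_factor(params$omega2, params$tau2, k)
  list(fiber_slope = lam * params$beta_f,
       pfas_slope = params$beta_x + params$gamma_x * params$beta_f * (1 - lam),
       lambda = lam)
}

#' Export a synthetic study to disk
#'
#' Writes the analytic-format CSV plus a truth file (JSON) holding the
#' generating parameters, seed, and latent fiber vector for test
#' harnesses.
#'
#' @param dataset A `synthetic_dataset`.
#' @param csv_path Output CSV path.
#' @param truth_path Optional JSON path for the truth file.
#' @return `csv_path`, invisibly.
#' @export
export_synthetic <- function(dataset, csv_path, truth_path = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  write_analytic_csv(dataset$records, csv_path)
  if (!is.null(truth_path)) {
    truth <- list(
      params = unclass(dataset$params),
      seed = dataset$seed,
      fiber_type = dataset$fiber_type,
      pfas_analyte = dataset$pfas_analyte,
      f_true = dataset$f_true
    )
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
               truth_path)
  }
  invisible(csv_path)
}
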