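#' Parameters of the latent-fiber outcome model
#'
#' Bundles every unknown of the three-part generative model used throughout
#' the package: an outcome regression, a latent-confounder regression, and a
#' classical replicate-measurement model,
#' \deqn{Y \mid X, F, C \sim N(\beta_0 + \beta_X X + \beta_F F + \beta_c^T C,\ \sigma^2)}
#' \deqn{F \mid X, C \sim N(\gamma_0 + \gamma_X X + \gamma_c^T C,\ \omega^2)}
#' \deqn{F_j^* \mid F \sim N(F,\ \tau^2), \quad j = 1, 2}
#' where \eqn{Y} is ln(serum total cholesterol, mg/dL), \eqn{X} is one serum
#' PFAS analyte (ng/mL), \eqn{F} is latent long-term fiber intake on the
#' ln(shifted, energy-adjusted g/d) scale, \eqn{F_1^*, F_2^*} are the two
#' dietary-recall replicates of \eqn{F}, and \eqn{C} are encoded secondary
#' covariates.
#'
#' @param beta0 Outcome-model intercept (ln mg/dL).
#' @param beta_x PFAS coefficient, per ng/mL.
#' @param beta_f Fiber coefficient, per ln-unit of shifted energy-adjusted
#'   fiber.
#' @param beta_c Named numeric vector of outcome-model covariate coefficients.
#' @param sigma2 Residual variance of the outcome model (> 0).
#' @param gamma0 Latent-fiber-model intercept (ln-scale).
#' @param gamma_x PFAS coefficient in the fiber model, per ng/mL.
#' @param gamma_c Named numeric vector of fiber-model covariate coefficients;
#'   names must match `beta_c`.
#' @param omega2 Residual (between-person) variance of latent fiber (> 0).
#' @param tau2 Replicate (within-person, day-to-day) measurement-error
#'   variance (>= 0).
#'
#' @return An object of class `model_parameters`.
#' @export
#' @examples
#' model_parameters(
#'   beta0 = 5.25, beta_x = 2.6e-3, beta_f = -0.03,
#'   beta_c = c(age = 1e-3), sigma2 = 0.03,
#'   gamma0 = 3.69, gamma_x = -0.009, gamma_c = c(age = 5e-4),
#'   omega2 = 0.01, tau2 = 0.02
#' )
model_parameters <- function(beta0, beta_x, beta_f, beta_c = numeric(0),
                             sigma2, gamma0, gamma_x, gamma_c = numeric(0),
                             omega2, tau2) {
  beta_c <- as.numeric_named(beta_c, "beta_c")
  gamma_c <- as.numeric_named(gamma_c, "gamma_c")
  if (!identical(names(beta_c), names(gamma_c))) {
    stop("`beta_c` and `gamma_c` must carry identical covariate names",
         call. = FALSE)
  }
  for (nm in c("beta0", "beta_x", "beta_f", "gamma0", "gamma_x")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be > 0", call. = FALSE)
  }
  if (!is.finite(omega2) || omega2 <= 0) {
    stop("`omega2` must be > 0", call. = FALSE)
  }
  if (!is.finite(tau2) || tau2 < 0) {
    stop("`tau2` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      beta0 = as.numeric(beta0), beta_x = as.numeric(beta_x),
      beta_f = as.numeric(beta_f), beta_c = beta_c,
      sigma2 = as.numeric(sigma2),
      gamma0 = as.numeric(gamma0), gamma_x = as.numeric(gamma_x),
      gamma_c = gamma_c, omega2 = as.numeric(omega2),
      tau2 = as.numeric(tau2)
    ),
    class = "model_parameters"
  )
}

# coerce to a named numeric vector (possibly length 0)
as.numeric_named <- function(x, what) {
  x <- unlist(x)
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", what), call. = FALSE)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(sprintf("`%s` must be fully named", what), call. = FALSE)
  }
  x
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Latent-fiber model parameters\n")
  cat(sprintf("  outcome:  beta0 = %.4g, beta_x = %.4g, beta_f = %.4g, sigma2 = %.4g\n",
              x$beta0, x$beta_x, x$beta_f, x$sigma2))
  cat(sprintf("  fiber:    gamma0 = %.4g, gamma_x = %.4g, omega2 = %.4g\n",
              x$gamma0, x$gamma_x, x$omega2))
  cat(sprintf("  replicates: tau2 = %.4g  (reliability of 2-day mean: %.3f)\n",
              x$tau2, attenuation_factor(x$omega2, x$tau2, 2)))
  if (length(x$beta_c)) {
    cat(sprintf("  %d covariate coefficient(s): %s\n", length(x$beta_c),
                paste(names(x$beta_c), collapse = ", ")))
  }
  invisible(x)
}

#' Flatten model parameters to a named vector
#'
#' Order: beta0, beta_x, beta_f, beta_c..., gamma0, gamma_x, gamma_c...,
#' sigma2, omega2, tau2. Used by the maximum-likelihood optimizer and the
#' posterior summaries so every fitting route reports parameters in one
#' layout.
#'
#' @param params A [model_parameters()] object.
#' @return Named numeric vector.
#' @export
flatten_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  bc <- params$beta_c
  gc <- params$gamma_c
  if (length(bc)) names(bc) <- paste0("beta_c.", names(bc))
  if (length(gc)) names(gc) <- paste0("gamma_c.", names(gc))
  c(beta0 = params$beta0, beta_x = params$beta_x, beta_f = params$beta_f,
    bc,
    gamma0 = params$gamma0, gamma_x = params$gamma_x, gc,
    sigma2 = params$sigma2, omega2 = params$omega2, tau2 = params$tau2)
}

#' Rebuild model parameters from a flat named vector
#'
#' Inverse of [flatten_parameters()] given the covariate names.
#'
#' @param theta Named numeric vector in [flatten_parameters()] layout.
#' @param covariate_names Character vector of covariate-column names.
#' @return A [model_parameters()] object.
#' @export
unflatten_parameters <- function(theta, covariate_names = character(0)) {
  pick <- function(nm) {
    if (!nm %in% names(theta)) stop("missing parameter: ", nm, call. = FALSE)
    unname(theta[[nm]])
  }
  vec <- function(prefix) {
    if (!length(covariate_names)) return(numeric(0))
    stats::setNames(
      vapply(paste0(prefix, ".", covariate_names), pick, numeric(1)),
      covariate_names
    )
  }
  model_parameters(
    beta0 = pick("beta0"), beta_x = pick("beta_x"), beta_f = pick("beta_f"),
    beta_c = vec("beta_c"), sigma2 = pick("sigma2"),
    gamma0 = pick("gamma0"), gamma_x = pick("gamma_x"),
    gamma_c = vec("gamma_c"), omega2 = pick("omega2"), tau2 = pick("tau2")
  )
}
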