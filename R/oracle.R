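# closed-form Gaussian marginal of the observables (F1*, F2*, Y | X, C):
# integrating the latent fiber out of the three-part model leaves a
# trivariate normal per subject, giving exact likelihood evaluation, an
# MLE, and an independent oracle for the MCMC fitter

#' Marginal moments of the observables for one subject
#'
#' Integrating latent fiber `F` out of the generative model gives, for a
#' subject with exposure `x` and covariate row `c_row`, a trivariate normal
#' for `(F1*, F2*, Y)` with
#' mean `(mu_F, mu_F, beta0 + beta_x x + beta_f mu_F + beta_c' c)` where
#' `mu_F = gamma0 + gamma_x x + gamma_c' c`, and covariance
#' `Var(Fj*) = omega2 + tau2`, `Cov(F1*, F2*) = omega2`,
#' `Cov(Fj*, Y) = beta_f * omega2`, `Var(Y) = sigma2 + beta_f^2 * omega2`.
#'
#' @param params A [model_parameters()] object.
#' @param x Scalar PFAS concentration (ng/mL).
#' @param c_row Named numeric vector of encoded covariates (may be empty).
#' @return A list: `mean` (length-3, ordered `F1*`, `F2*`, `Y`) and `cov`
#'   (3 x 3 symmetric positive-definite matrix).
#' @export
marginal_moments <- function(params, x, c_row = numeric(0)) {
  stopifnot(inherits(params, "model_parameters"))
  if (length(params$beta_c)) {
    c_row <- c_row[names(params$beta_c)]
    if (anyNA(c_row)) stop("`c_row` must carry all covariates named in the parameters",
                           call. = FALSE)
  }
  mu_f <- params$gamma0 + params$gamma_x * x +
    sum(params$gamma_c * c_row)
  mu_y <- params$beta0 + params$beta_x * x + params$beta_f * mu_f +
    sum(params$beta_c * c_row)
  S <- marginal_cov(params)
  list(mean = stats::setNames(c(mu_f, mu_f, mu_y), c("f_star_1", "f_star_2", "y")),
       cov = S)
}

# the 3x3 observable covariance, identical across subjects
marginal_cov <- function(params) {
  with(params, {
    S <- matrix(c(
      omega2 + tau2, omega2,        beta_f * omega2,
      omega2,        omega2 + tau2, beta_f * omega2,
      beta_f * omega2, beta_f * omega2, sigma2 + beta_f^2 * omega2
    ), 3, 3)
    dimnames(S) <- rep(list(c("f_star_1", "f_star_2", "y")), 2)
    S
  })
}

#' Marginal log-likelihood of a design bundle
#'
#' Sum over subjects of the trivariate-normal log-density of
#' `(F1*, F2*, Y)` at the subject-specific moments of
#' [marginal_moments()]. Because the covariance is identical across
#' subjects, its Cholesky factor is computed once per parameter value.
#'
#' @param params A [model_parameters()] with `tau2 > 0` (the covariance is
#'   singular at `tau2 = 0`).
#' @param bundle A [design_bundle()] with fiber replicates; covariate
#'   columns must match the names in `params`.
#' @return The log-likelihood (a scalar).
#' @export
marginal_loglik <- function(params, bundle) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(bundle, "design_bundle"))
  if (is.null(bundle$f_star_1)) {
    stop("bundle has no fiber replicates", call. = FALSE)
  }
  cn <- names(params$beta_c)
  if (!all(cn %in% colnames(bundle$c))) {
    stop("parameter covariate names not found in bundle", call. = FALSE)
  }
  C <- bundle$c[, cn, drop = FALSE]
  mu_f <- params$gamma0 + params$gamma_x * bundle$x +
    drop(C %*% params$gamma_c)
  mu_y <- params$beta0 + params$beta_x * bundle$x + params$beta_f * mu_f +
    drop(C %*% params$beta_c)
  S <- marginal_cov(params)
  L <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(L)) {
    stop("parameter error: marginal covariance is not positive definite",
         call. = FALSE)
  }
  R <- rbind(bundle$f_star_1 - mu_f, bundle$f_star_2 - mu_f, bundle$y - mu_y)
  z <- backsolve(L, R, transpose = TRUE)
  n <- bundle$n
  -n * (3 / 2 * log(2 * pi) + sum(log(diag(L)))) - 0.5 * sum(z * z)
}

# naive starting values from two OLS fits on the observed data
.naive_start <- function(bundle) {
  cn <- colnames(bundle$c)
  Xf <- cbind(1, bundle$x, bundle$c)
  gfit <- stats::lm.fit(Xf, bundle$f_bar)
  tau2 <- stats::var(bundle$f_star_1 - bundle$f_star_2) / 2
  omega2 <- max(stats::var(gfit$residuals) - tau2 / 2, 1e-6)
  Xy <- cbind(1, bundle$x, bundle$f_bar, bundle$c)
  yfit <- stats::lm.fit(Xy, bundle$y)
  sigma2 <- max(stats::var(yfit$residuals), 1e-8)
  model_parameters(
    beta0 = yfit$coefficients[[1L]], beta_x = yfit$coefficients[[2L]],
    beta_f = yfit$coefficients[[3L]],
    beta_c = stats::setNames(yfit$coefficients[-(1:3)], cn),
    sigma2 = sigma2,
    gamma0 = gfit$coefficients[[1L]], gamma_x = gfit$coefficients[[2L]],
    gamma_c = stats::setNames(gfit$coefficients[-(1:2)], cn),
    omega2 = omega2, tau2 = max(tau2, 1e-8)
  )
}

# flat vector <-> optimizer scale (variances on the log scale)
.theta_from_params <- function(params) {
  th <- flatten_parameters(params)
  for (v in c("sigma2", "omega2", "tau2")) th[[v]] <- log(th[[v]])
  names(th)[names(th) %in% c("sigma2", "omega2", "tau2")] <-
    paste0("log_", c("sigma2", "omega2", "tau2"))
  th
}

.params_from_theta <- function(theta, covariate_names) {
  for (v in c("sigma2", "omega2", "tau2")) {
    theta[[v]] <- exp(theta[[paste0("log_", v)]])
  }
  theta <- theta[!grepl("^log_", names(theta))]
  unflatten_parameters(theta, covariate_names)
}

#' Maximum-likelihood estimation under the marginal model
#'
#' Numerically maximizes [marginal_loglik()] over all model parameters,
#' with the three variances optimized on the log scale so positivity is
#' implicit. Starting values default to naive OLS fits of the observed
#' data (the fiber replicate-difference variance halves into the starting
#' `tau2`). Asymptotic standard errors come from the inverse observed
#' information (finite-difference Hessian at the optimum), delta-rule
#' transformed for the variances.
#'
#' @param bundle A [design_bundle()] with fiber replicates.
#' @param start Optional [model_parameters()] starting point.
#' @param control Passed to [stats::optim()] (method `"BFGS"`); `maxit`
#'   defaults to 500 and `reltol` to 1e-10.
#' @return An object of class `marginal_mle`: `params` (the estimates),
#'   `se` (named, natural scale), `vcov` (on the optimizer scale),
#'   `loglik`, `gradient_norm`, `convergence` (0 = converged), and
#'   `counts`.
#' @export
marginal_mle <- function(bundle, start = NULL, control = list()) {
  stopifnot(inherits(bundle, "design_bundle"))
  if (is.null(start)) start <- .naive_start(bundle)
  cn <- names(start$beta_c)
  theta0 <- .theta_from_params(start)
  negll <- function(theta) {
    names(theta) <- names(theta0)
    p <- tryCatch(.params_from_theta(theta, cn), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- tryCatch(marginal_loglik(p, bundle), error = function(e) -1e10)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  control <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  opt <- stats::optim(theta0, negll, method = "BFGS", control = control,
                      hessian = TRUE)
  if (opt$convergence != 0) {
    stop("marginal MLE did not converge (optim code ", opt$convergence,
         "); counts = ", paste(opt$counts, collapse = "/"), call. = FALSE)
  }
  theta_hat <- opt$par
  grad <- numDeriv::grad(negll, theta_hat)
  vcov <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, length(theta_hat), length(theta_hat))
  })
  dimnames(vcov) <- list(names(theta_hat), names(theta_hat))
  se_theta <- sqrt(pmax(diag(vcov), 0))
  params_hat <- .params_from_theta(theta_hat, cn)
  # delta rule: SE(v) = v * SE(log v)
  se <- se_theta
  for (v in c("sigma2", "omega2", "tau2")) {
    se[[paste0("log_", v)]] <- params_hat[[v]] * se[[paste0("log_", v)]]
  }
  names(se) <- sub("^log_", "", names(se))
  structure(
    list(params = params_hat, se = se, vcov = vcov,
         loglik = -opt$value, gradient_norm = sqrt(sum(grad^2)),
         convergence = opt$convergence, counts = opt$counts),
    class = "marginal_mle"
  )
}

#' @export
print.marginal_mle <- function(x, ...) {
  cat(sprintf("Marginal-likelihood MLE: loglik = %.3f, |grad| = %.3g\n",
              x$loglik, x$gradient_norm))
  key <- c("beta_x", "beta_f", "sigma2", "omega2", "tau2")
  est <- flatten_parameters(x$params)
  for (nm in key) {
    cat(sprintf("  %-7s %12.5g (SE %.4g)\n", nm, est[[nm]], x$se[[nm]]))
  }
  invisible(x)
}
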