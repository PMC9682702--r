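# Bayesian fitting of the latent-fiber measurement-error model.
#
# The full model — Gaussian outcome regression, Gaussian latent-confounder
# regression, and Gaussian replicate measurements — is conditionally
# conjugate in every block, so the posterior is sampled by a blocked Gibbs
# sampler: latent fiber from its exact normal full conditional (vectorized
# over subjects), each regression-coefficient block from a joint
# multivariate normal, and each variance from an inverse gamma.

#' Prior specification for the Bayesian model
#'
#' Regression coefficients get independent normal priors; variances get
#' inverse-gamma priors (shape, rate), the conditionally conjugate family
#' for Gaussian variances. Defaults are weakly informative: coefficient
#' priors centered at zero with a large standard deviation relative to each
#' variable's scale, and near-flat variance priors. Informative priors are
#' configuration, not code: supply named means/sds to reproduce a published
#' prior set.
#'
#' @param coef_mean Scalar or named vector of prior means for regression
#'   coefficients (names in [flatten_parameters()] layout, e.g. `beta_f`,
#'   `gamma_x`, `beta_c.age`). Unnamed scalar applies to all.
#' @param coef_sd Scalar or named vector of prior standard deviations,
#'   recycled the same way. Default 10.
#' @param var_shape,var_rate Inverse-gamma shape and rate shared by
#'   `sigma2`, `omega2`, `tau2`. Defaults 0.001/0.001 (near-flat).
#' @param informative Logical flag recording whether this is an informative
#'   set; purely descriptive.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coef_mean = 0, coef_sd = 10,
                       var_shape = 0.001, var_rate = 0.001,
                       informative = FALSE) {
  if (any(coef_sd <= 0)) stop("prior sds must be > 0", call. = FALSE)
  if (var_shape <= 0 || var_rate <= 0) {
    stop("variance prior shape/rate must be > 0", call. = FALSE)
  }
  structure(
    list(coef_mean = coef_mean, coef_sd = coef_sd,
         var_shape = var_shape, var_rate = var_rate,
         informative = isTRUE(informative)),
    class = "prior_spec"
  )
}

# resolve scalar-or-named prior settings to a vector aligned with `terms`
.prior_vec <- function(x, terms, default) {
  out <- rep(if (length(x) == 1L && is.null(names(x))) x else default,
             length(terms))
  names(out) <- terms
  if (!is.null(names(x))) {
    hit <- intersect(names(x), terms)
    out[hit] <- x[hit]
  }
  out
}

# one conjugate draw of a coefficient block:
# y ~ N(X b, s2), b ~ N(m0, diag(sd0^2))
.draw_coef <- function(X, y, s2, m0, sd0) {
  p <- ncol(X)
  prior_prec <- 1 / sd0^2
  Vinv <- crossprod(X) / s2 + diag(prior_prec, p)
  b <- drop(crossprod(X, y)) / s2 + prior_prec * m0
  U <- chol(Vinv)
  mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
  mu + backsolve(U, stats::rnorm(p))
}

#' Fit the latent-fiber model by Markov chain Monte Carlo
#'
#' Samples the joint posterior of all model parameters and the n latent
#' fiber values with a blocked Gibbs sampler (see the package vignette for
#' the full conditionals). Each chain runs `iterations` sweeps and the
#' first `warmup_fraction` of each chain is discarded. When the bundle has
#' no fiber replicates the fiber-free outcome regression is fitted instead
#' (the Bayesian analogue of the unadjusted OLS model).
#'
#' Chain count, iteration count, and warmup fraction are honored from
#' `settings`; the Hamiltonian-specific settings `max_tree_depth` and
#' `target_accept` are recorded in the result for provenance but have no
#' role in a Gibbs sampler. Results are reproducible given identical
#' `seed`, data, and settings.
#'
#' @param bundle A [design_bundle()].
#' @param priors A [prior_spec()]; `NULL` uses the defaults.
#' @param settings List overriding `chains` (default 4), `iterations`
#'   (2500), `warmup_fraction` (0.5), `rhat_threshold` (1.01).
#' @param seed Integer seed.
#' @return An object of class `bayes_fit`: `draws` (list of kept-draw
#'   matrices, one per chain, columns in [flatten_parameters()] layout),
#'   `summary` (a `posterior_summary`), `f_post_mean` (posterior mean of
#'   each subject's latent fiber; `NULL` for the fiber-free model),
#'   `settings`, `priors`, `seed`.
#' @export
fit_bayes <- function(bundle, priors = NULL, settings = list(), seed = 1L) {
  stopifnot(inherits(bundle, "design_bundle"))
  if (is.null(priors)) priors <- prior_spec()
  stopifnot(inherits(priors, "prior_spec"))
  defaults <- list(chains = 4L, iterations = 2500L, warmup_fraction = 0.5,
                   rhat_threshold = 1.01, max_tree_depth = 15L,
                   target_accept = 0.8)
  settings <- utils::modifyList(defaults, settings)
  if (settings$chains < 1L) stop("need at least one chain", call. = FALSE)
  n_iter <- as.integer(settings$iterations)
  n_warm <- as.integer(floor(settings$warmup_fraction * n_iter))
  n_keep <- n_iter - n_warm
  if (n_keep < 2L) stop("too few kept iterations", call. = FALSE)

  has_fiber <- !is.null(bundle$f_star_1)
  n <- bundle$n
  C <- bundle$c
  cn <- colnames(C)
  y <- bundle$y
  x <- bundle$x

  a0 <- priors$var_shape
  b0 <- priors$var_rate

  if (has_fiber) {
    beta_terms <- c("beta0", "beta_x", "beta_f",
                    if (length(cn)) paste0("beta_c.", cn))
    gamma_terms <- c("gamma0", "gamma_x",
                     if (length(cn)) paste0("gamma_c.", cn))
    par_names <- c(beta_terms, gamma_terms, "sigma2", "omega2", "tau2")
    Xg <- cbind(1, x, C)
    XgtXg <- crossprod(Xg)
    start <- .naive_start(bundle)
    th0 <- flatten_parameters(start)
  } else {
    beta_terms <- c("beta0", "beta_x", if (length(cn)) paste0("beta_c.", cn))
    gamma_terms <- character(0)
    par_names <- c(beta_terms, "sigma2")
    Xy0 <- cbind(1, x, C)
    fit0 <- stats::lm.fit(Xy0, y)
    th0 <- c(stats::setNames(fit0$coefficients, beta_terms),
             sigma2 = max(stats::var(fit0$residuals), 1e-8))
  }

  m_beta <- .prior_vec(priors$coef_mean, beta_terms, 0)
  s_beta <- .prior_vec(priors$coef_sd, beta_terms, 10)
  m_gamma <- .prior_vec(priors$coef_mean, gamma_terms, 0)
  s_gamma <- .prior_vec(priors$coef_sd, gamma_terms, 10)

  set.seed(seed)
  chains <- vector("list", settings$chains)
  f_accum <- if (has_fiber) numeric(n)
  f_draws_total <- 0L

  for (ch in seq_len(settings$chains)) {
    kept <- matrix(NA_real_, n_keep, length(par_names),
                   dimnames = list(NULL, par_names))
    # overdispersed start: jitter naive estimates
    jit <- function(v) v + stats::rnorm(length(v), 0, pmax(abs(v), 0.02) * 0.2)
    if (has_fiber) {
      beta <- jit(th0[beta_terms])
      gam <- jit(th0[gamma_terms])
      sigma2 <- th0[["sigma2"]] * exp(stats::runif(1, -0.4, 0.4))
      omega2 <- th0[["omega2"]] * exp(stats::runif(1, -0.4, 0.4))
      tau2 <- th0[["tau2"]] * exp(stats::runif(1, -0.4, 0.4))
      f <- bundle$f_bar
      fsum <- bundle$f_star_1 + bundle$f_star_2
      for (it in seq_len(n_iter)) {
        # latent fiber: exact normal full conditional, vectorized
        bf <- beta[[3L]]
        eta_yf <- drop(cbind(1, x, C) %*% beta[-3L]) # outcome predictor sans F
        mu_f0 <- drop(Xg %*% gam)
        prec <- 1 / omega2 + 2 / tau2 + bf^2 / sigma2
        m <- (mu_f0 / omega2 + fsum / tau2 + bf * (y - eta_yf) / sigma2) / prec
        f <- stats::rnorm(n, m, sqrt(1 / prec))
        # outcome coefficients
        Xy <- cbind(1, x, f, C)
        beta <- .draw_coef(Xy, y, sigma2, m_beta, s_beta)
        # fiber-model coefficients
        gam <- .draw_coef(Xg, f, omega2, m_gamma, s_gamma)
        # variances: conjugate inverse gamma
        ry <- y - drop(Xy %*% beta)
        sigma2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(ry^2) / 2)
        rf <- f - drop(Xg %*% gam)
        omega2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(rf^2) / 2)
        rt <- sum((bundle$f_star_1 - f)^2) + sum((bundle$f_star_2 - f)^2)
        tau2 <- 1 / stats::rgamma(1, a0 + n, b0 + rt / 2)
        if (it > n_warm) {
          kept[it - n_warm, ] <- c(beta, gam, sigma2, omega2, tau2)
          f_accum <- f_accum + f
          f_draws_total <- f_draws_total + 1L
        }
      }
    } else {
      beta <- jit(th0[beta_terms])
      sigma2 <- th0[["sigma2"]] * exp(stats::runif(1, -0.4, 0.4))
      for (it in seq_len(n_iter)) {
        beta <- .draw_coef(Xy0, y, sigma2, m_beta, s_beta)
        ry <- y - drop(Xy0 %*% beta)
        sigma2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(ry^2) / 2)
        if (it > n_warm) kept[it - n_warm, ] <- c(beta, sigma2)
      }
    }
    chains[[ch]] <- kept
  }

  summ <- summarize_posterior(chains,
                              rhat_threshold = settings$rhat_threshold)
  structure(
    list(draws = chains, summary = summ,
         f_post_mean = if (has_fiber) f_accum / f_draws_total,
         settings = settings, priors = priors, seed = as.integer(seed),
         has_fiber = has_fiber),
    class = "bayes_fit"
  )
}

#' @export
print.bayes_fit <- function(x, ...) {
  s <- x$summary$table
  cat(sprintf("Bayesian fit: %d chain(s) x %d kept draws%s\n",
              length(x$draws), nrow(x$draws[[1L]]),
              if (x$has_fiber) ", latent fiber sampled" else " (no fiber)"))
  key <- intersect(c("beta_x", "beta_f", "sigma2", "omega2", "tau2"),
                   s$parameter)
  print(s[s$parameter %in% key,
          c("parameter", "mean", "sd", "q2.5", "q97.5", "rhat", "ess")],
        row.names = FALSE, digits = 4)
  if (length(x$summary$warnings)) {
    cat("convergence warnings:", length(x$summary$warnings), "\n")
  }
  invisible(x)
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, SD, and 2.5/50/97.5 percentiles, plus
#' split-R-hat (each chain halved, within/between-variance ratio) and
#' effective sample size (summed over chains). With a single chain the
#' diagnostics are reported as `NA` and flagged unavailable.
#'
#' @param draws A list of kept-draw matrices (one per chain, equal
#'   dimensions, named columns) or a single matrix.
#' @param rhat_threshold Parameters with split-R-hat above this raise a
#'   warning and are listed in the result's `warnings`. Default 1.01.
#' @return An object of class `posterior_summary`: `table` (a data.frame),
#'   `n_chains`, `n_kept`, `divergences` (always 0 for a Gibbs sampler),
#'   `warnings`.
#' @export
summarize_posterior <- function(draws, rhat_threshold = 1.01) {
  if (is.matrix(draws)) draws <- list(draws)
  stopifnot(is.list(draws), length(draws) >= 1L)
  dims <- vapply(draws, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    stop("all chains must have identical dimensions", call. = FALSE)
  }
  pn <- colnames(draws[[1L]])
  all_draws <- do.call(rbind, draws)
  qs <- apply(all_draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  single <- length(draws) == 1L
  rhat <- vapply(pn, function(p) {
    split_rhat(lapply(draws, function(m) m[, p]))
  }, numeric(1))
  ess <- if (single) rep(NA_real_, length(pn)) else {
    mc <- coda::mcmc.list(lapply(draws, coda::mcmc))
    as.numeric(coda::effectiveSize(mc))[seq_along(pn)]
  }
  if (single) rhat[] <- NA_real_
  tab <- data.frame(
    parameter = pn,
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
    rhat = rhat, ess = ess,
    row.names = NULL, stringsAsFactors = FALSE
  )
  warnings <- character(0)
  if (single) {
    warnings <- "single chain: split-R-hat and ESS unavailable"
  } else {
    bad <- tab$parameter[!is.na(tab$rhat) & tab$rhat > rhat_threshold]
    if (length(bad)) {
      warnings <- sprintf("split-R-hat > %.3g for: %s", rhat_threshold,
                          paste(bad, collapse = ", "))
      warning(warnings, call. = FALSE)
    }
  }
  structure(
    list(table = tab, n_chains = length(draws), n_kept = nrow(draws[[1L]]),
         divergences = 0L, warnings = warnings),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary: %d chain(s) x %d kept draws\n",
              x$n_chains, x$n_kept))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Split-R-hat for one parameter
#'
#' Each chain is split in half and the standard potential-scale-reduction
#' statistic is computed on the resulting half-chains:
#' `sqrt(((m - 1)/m * W + B/m) / W)` with `m` the half-chain length, `W`
#' the mean within-half variance, and `B` the between-half variance of the
#' half means scaled by `m`. Returns `NA` for a single chain and 1 for
#' exactly constant draws.
#'
#' @param chains A list of numeric vectors (one per chain) or a single
#'   vector.
#' @return The split-R-hat statistic.
#' @export
split_rhat <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  if (length(chains) < 2L) return(NA_real_)
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[(length(v) - h + 1L):length(v)])
  }), recursive = FALSE)
  m <- length(halves[[1L]])
  k <- length(halves)
  W <- mean(vapply(halves, stats::var, numeric(1)))
  mus <- vapply(halves, mean, numeric(1))
  B <- m * stats::var(mus)
  if (W == 0) return(if (B == 0 || is.na(B)) 1 else Inf)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Bayesian change-in-estimate comparison
#'
#' Applies the same change-in-estimate rule as [assess_confounding()] to
#' the posterior-mean PFAS coefficients of a fiber-unadjusted and a
#' fiber-adjusted Bayesian fit.
#'
#' @param fit_unadjusted,fit_adjusted `bayes_fit` objects on the same
#'   sample.
#' @param pfas_term Parameter name, default `"beta_x"`.
#' @param threshold Percent threshold for the flag, default 10.
#' @return A `confounding_assessment`.
#' @export
compare_models <- function(fit_unadjusted, fit_adjusted,
                           pfas_term = "beta_x", threshold = 10) {
  grab <- function(fit) {
    stopifnot(inherits(fit, "bayes_fit"))
    tab <- fit$summary$table
    if (!pfas_term %in% tab$parameter) {
      stop("parameter '", pfas_term, "' not in fit", call. = FALSE)
    }
    list(coefficients = stats::setNames(tab$mean[tab$parameter == pfas_term],
                                        pfas_term),
         n = NULL)
  }
  assess_confounding(grab(fit_unadjusted), grab(fit_adjusted),
                     pfas_term = pfas_term, threshold = threshold)
}

#' Extract posterior point estimates as model parameters
#'
#' Posterior means of a fiber-adjusted `bayes_fit`, shaped as a
#' [model_parameters()] object.
#'
#' @param fit A `bayes_fit` with latent fiber.
#' @return A [model_parameters()].
#' @export
posterior_parameters <- function(fit) {
  stopifnot(inherits(fit, "bayes_fit"))
  if (!fit$has_fiber) stop("fiber-free fit has no full parameter set",
                           call. = FALSE)
  tab <- fit$summary$table
  theta <- stats::setNames(tab$mean, tab$parameter)
  cn <- sub("^beta_c\\.", "", grep("^beta_c\\.", tab$parameter, value = TRUE))
  unflatten_parameters(theta, cn)
}
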