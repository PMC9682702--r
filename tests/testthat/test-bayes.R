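# Gibbs sampler for the latent-fiber model, posterior summaries,
# convergence diagnostics, Bayesian change-in-estimate

test_that("posterior summary diagnostics behave on known draw patterns", {
  set.seed(5)
  # iid standard-normal chains: R-hat ~ 1, ESS ~ total draws
  chains <- lapply(1:4, function(i) {
    matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "theta"))
  })
  s <- summarize_posterior(chains)
  expect_gte(s$table$rhat, 1 - 1e-6)
  expect_lte(s$table$rhat, 1.01)
  expect_gt(s$table$ess, 0.7 * 4000)
  expect_equal(s$table$mean, 0, tolerance = 0.1)
  expect_equal(s$table$q2.5, qnorm(0.025), tolerance = 0.15)

  # two chains stuck at different modes: R-hat blows up
  far <- list(matrix(rnorm(500, 0), ncol = 1, dimnames = list(NULL, "t")),
              matrix(rnorm(500, 5), ncol = 1, dimnames = list(NULL, "t")))
  expect_warning(s2 <- summarize_posterior(far), "split-R-hat")
  expect_gt(s2$table$rhat, 1.1)

  # constant draws: SD 0, all percentiles equal, R-hat defined as 1
  const <- lapply(1:2, function(i) {
    matrix(2.5, 100, 1, dimnames = list(NULL, "k"))
  })
  s3 <- summarize_posterior(const)
  expect_equal(s3$table$sd, 0)
  expect_equal(s3$table$q2.5, s3$table$q97.5)
  expect_equal(s3$table$rhat, 1)

  # single chain: diagnostics flagged unavailable
  s4 <- summarize_posterior(chains[[1]])
  expect_true(is.na(s4$table$rhat))
  expect_match(s4$warnings, "single chain")
})

test_that("identical seeds reproduce the posterior exactly", {
  b <- sim_bundle(tiny_params(), 150, seed = 2)
  light <- list(chains = 2L, iterations = 300L)
  f1 <- suppressWarnings(fit_bayes(b, settings = light, seed = 99))
  f2 <- suppressWarnings(fit_bayes(b, settings = light, seed = 99))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_bayes(b, settings = light, seed = 100))
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("posterior matches the marginal MLE under weak priors", {
  p <- tiny_params()
  b <- sim_bundle(p, 1000, seed = 14)
  fb <- suppressWarnings(fit_bayes(b, seed = 8))
  m <- marginal_mle(b)
  est <- flatten_parameters(m$params)
  tab <- fb$summary$table
  z <- (tab$mean - est[tab$parameter]) / tab$sd
  expect_true(all(abs(z) < 3),
              info = paste(tab$parameter, round(z, 2), collapse = "; "))
  # sampler contract: 4 chains x 2500 iterations, warmup 0.5 -> 5000 kept
  expect_length(fb$draws, 4L)
  expect_equal(nrow(fb$draws[[1]]), 1250L)
})

test_that("tight priors dominate a tiny sample", {
  b <- sim_bundle(tiny_params(), 10, seed = 4)
  pri <- prior_spec(
    coef_mean = c(beta_x = 0.7, gamma_x = -1.2),
    coef_sd = c(beta_x = 1e-4, gamma_x = 1e-4)
  )
  fb <- suppressWarnings(
    fit_bayes(b, priors = pri, settings = list(chains = 2L,
                                               iterations = 1000L),
              seed = 3))
  tab <- fb$summary$table
  expect_equal(tab$mean[tab$parameter == "beta_x"], 0.7, tolerance = 1e-2)
  expect_equal(tab$mean[tab$parameter == "gamma_x"], -1.2, tolerance = 1e-2)
  expect_lt(tab$sd[tab$parameter == "beta_x"], 5e-4)
})

test_that("with error-free replicates the posterior concentrates at the naive OLS slope", {
  p <- tiny_params(tau2 = 1e-12)
  set.seed(23)
  n <- 800
  x <- rlnorm(n, log(2), 0.5)
  cm <- cbind(age = rnorm(n, 0, 15))
  lat <- simulate_latent(p, x, cm)
  b <- design_bundle(lat$y, x, lat$f_star_1, lat$f_star_2, cm)
  ols <- fit_ols(b, include_fiber = TRUE)
  fb <- suppressWarnings(fit_bayes(b, seed = 6))
  tab <- fb$summary$table
  bf <- tab[tab$parameter == "beta_f", ]
  expect_lt(abs(bf$mean - ols$coefficients[["f_bar"]]), 3 * bf$sd)
  expect_equal(bf$mean, ols$coefficients[["f_bar"]], tolerance = 0.05)
})

test_that("the posterior de-attenuates the fiber slope and recovers latent fiber", {
  # strong-signal regime so ordering is not noise-dominated
  p <- tiny_params(beta_f = -0.5, tau2 = 0.08)
  hits <- 0
  reps <- 10
  for (i in seq_len(reps)) {
    s <- sim_bundle(p, 500, seed = 600 + i, keep_truth = TRUE)
    b <- s$bundle
    naive <- fit_ols(b, include_fiber = TRUE)$coefficients[["f_bar"]]
    fb <- suppressWarnings(
      fit_bayes(b, settings = list(chains = 2L, iterations = 1200L),
                seed = i))
    post_bf <- fb$summary$table$mean[fb$summary$table$parameter == "beta_f"]
    if (post_bf < naive) hits <- hits + 1
    if (i == 1) {
      # latent recovery: posterior mean of F_i tracks truth better than
      # the replicate mean does
      expect_gt(cor(fb$f_post_mean, s$f), cor(b$f_bar, s$f))
    }
  }
  expect_gte(hits, 9) # de-attenuation in at least 90% of replicates
})

test_that("Bayesian change-in-estimate mirrors the OLS criterion", {
  mk <- function(bx) {
    structure(list(summary = list(table = data.frame(
      parameter = "beta_x", mean = bx, stringsAsFactors = FALSE
    ))), class = "bayes_fit")
  }
  a <- compare_models(mk(2.66e-3), mk(2.49e-3))
  expect_equal(round(a$percent_change, 1), 6.4)
  expect_false(a$flagged)
  expect_equal(compare_models(mk(1e-3), mk(1e-3))$percent_change, 0)
})

test_that("independent MCMC software agrees with the Gibbs sampler", {
  skip_if_not_installed("rjags")
  p <- model_parameters(beta0 = 5.2, beta_x = 0.003, beta_f = -0.3,
                        sigma2 = 0.03, gamma0 = 3.7, gamma_x = -0.01,
                        omega2 = 0.04, tau2 = 0.08)
  set.seed(3)
  n <- 300
  x <- rlnorm(n, log(2), 0.5)
  lat <- simulate_latent(p, x)
  b <- design_bundle(lat$y, x, lat$f_star_1, lat$f_star_2)
  fb <- suppressWarnings(fit_bayes(b, settings = list(iterations = 4000L),
                                   seed = 2))
  model_txt <- "model {
    for (i in 1:n) {
      f[i] ~ dnorm(gamma0 + gamma_x * x[i], 1 / omega2)
      y[i] ~ dnorm(beta0 + beta_x * x[i] + beta_f * f[i], 1 / sigma2)
      f1[i] ~ dnorm(f[i], 1 / tau2)
      f2[i] ~ dnorm(f[i], 1 / tau2)
    }
    beta0 ~ dnorm(0, 0.01); beta_x ~ dnorm(0, 0.01); beta_f ~ dnorm(0, 0.01)
    gamma0 ~ dnorm(0, 0.01); gamma_x ~ dnorm(0, 0.01)
    sigma2 <- 1 / ps; ps ~ dgamma(0.001, 0.001)
    omega2 <- 1 / po; po ~ dgamma(0.001, 0.001)
    tau2 <- 1 / pt; pt ~ dgamma(0.001, 0.001)
  }"
  jm <- rjags::jags.model(
    textConnection(model_txt),
    data = list(n = n, x = x, y = b$y, f1 = b$f_star_1, f2 = b$f_star_2),
    n.chains = 2, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  sm <- rjags::coda.samples(
    jm, c("beta_x", "beta_f", "gamma_x", "sigma2", "omega2", "tau2"),
    4000, progress.bar = "none")
  js <- summary(sm)$statistics
  tab <- fb$summary$table
  for (nm in rownames(js)) {
    mine <- tab$mean[tab$parameter == nm]
    sd_ <- tab$sd[tab$parameter == nm]
    expect_lt(abs(mine - js[nm, "Mean"]), 1.5 * sd_, label = nm)
  }
})
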