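# OLS reference analysis: normal-equations equivalence, AIC, the
# change-in-estimate criterion, the quadratic sensitivity check

test_that("fit_ols matches an explicit normal-equations solve on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(40:100, 1)
    b <- sim_bundle(tiny_params(), n, seed = seed + 100)
    fit <- fit_ols(b, include_fiber = TRUE)
    X <- cbind(1, b$x, b$f_bar, b$c)
    beta <- solve(t(X) %*% X, t(X) %*% b$y)
    expect_equal(unname(fit$coefficients), as.numeric(beta),
                 tolerance = 1e-9)
    rss <- sum((b$y - X %*% beta)^2)
    se <- sqrt(diag(solve(t(X) %*% X)) * rss / (n - ncol(X)))
    expect_equal(unname(fit$standard_errors), as.numeric(se),
                 tolerance = 1e-8)
  }
})

test_that("AIC equals the stats::AIC of the equivalent lm fit", {
  b <- sim_bundle(tiny_params(), 60, seed = 5)
  fit <- fit_ols(b, include_fiber = TRUE)
  lmfit <- lm(b$y ~ b$x + b$f_bar + b$c)
  expect_equal(fit$aic, AIC(lmfit), tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(logLik(lmfit)), tolerance = 1e-8)
})

test_that("noise-free data reproduce the generating coefficients exactly", {
  # outcome and replicate noise off; omega2 stays positive so latent fiber
  # is not an exact linear function of (x, age) and beta_f is identified
  p <- tiny_params(tau2 = 1e-12)
  p$sigma2 <- 1e-12
  set.seed(2)
  x <- rlnorm(50, log(2), 0.5)
  cm <- cbind(age = rnorm(50, 0, 15))
  lat <- simulate_latent(p, x, cm)
  b <- design_bundle(lat$y, x, lat$f_star_1, lat$f_star_2, cm)
  fit <- fit_ols(b, include_fiber = TRUE)
  expect_lt(abs(fit$coefficients[["x"]] - p$beta_x), 1e-5)
  expect_lt(abs(fit$coefficients[["f_bar"]] - p$beta_f), 1e-5)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - p$beta0), 1e-4)
})

test_that("change-in-estimate arithmetic and the 10% flag", {
  mk <- function(bx) list(coefficients = c(x = bx), n = 100L)
  a <- assess_confounding(mk(2.66e-3), mk(2.49e-3))
  expect_equal(a$percent_change, 100 * (2.66 - 2.49) / 2.66)
  expect_equal(round(a$percent_change, 1), 6.4)
  expect_false(a$flagged)

  a2 <- assess_confounding(mk(2.59e-3), mk(2.45e-3))
  expect_equal(round(a2$percent_change, 1), 5.4)
  expect_false(a2$flagged)

  expect_equal(assess_confounding(mk(1), mk(1))$percent_change, 0)
  expect_true(assess_confounding(mk(1), mk(0.85))$flagged)
  expect_true(assess_confounding(mk(1), mk(1.2))$flagged) # |change| rule
  expect_error(assess_confounding(mk(0), mk(1)), "zero")
  expect_error(
    assess_confounding(list(coefficients = c(x = 1), n = 10L), mk(2)),
    "different samples")
})

test_that("rank-deficient designs are rejected with the offending column named", {
  b <- sim_bundle(tiny_params(), 50, seed = 6)
  b$c <- cbind(b$c, age_copy = b$c[, "age"])
  expect_error(fit_ols(b, TRUE), "age_copy")
  # constant exposure makes the quadratic column collinear with intercept
  b2 <- design_bundle(y = rnorm(30), x = rep(2, 30))
  expect_error(quadratic_sensitivity(b2, include_fiber = FALSE), "x2|rank")
})

test_that("AIC sensitivity prefers the generating PFAS functional form", {
  # linear truth: the quadratic term should rarely be worth its parameter;
  # quadratic truth: it must be strongly favored
  p <- tiny_params()
  delta_lin <- delta_quad <- numeric(10)
  for (i in 1:10) {
    set.seed(400 + i)
    n <- 2000
    x <- rlnorm(n, log(2), 0.5)
    cm <- cbind(age = rnorm(n, 0, 15))
    lat <- simulate_latent(p, x, cm)
    b <- design_bundle(lat$y, x, lat$f_star_1, lat$f_star_2, cm)
    delta_lin[i] <- quadratic_sensitivity(b)$delta_aic
    y_quad <- lat$y + 0.02 * (x - mean(x))^2
    bq <- design_bundle(y_quad, x, lat$f_star_1, lat$f_star_2, cm)
    delta_quad[i] <- quadratic_sensitivity(bq)$delta_aic
  }
  # delta_aic = aic_linear - aic_quadratic: positive favors quadratic
  expect_lt(median(delta_lin), 2)
  expect_true(all(delta_quad > 10))
})

test_that("the nine-model grid shares one n and shows no confounding when beta_f = 0", {
  p <- default_parameters()
  p$beta_f <- 0
  p$beta_x <- 0.02 # strong exposure effect keeps the percent-change
                   # denominator away from zero at this n
  d <- generate_synthetic(3000, params = p, seed = 12)
  t1 <- run_table1(d$records)
  expect_length(t1$fits, 9L)
  expect_true(all(vapply(t1$fits, function(f) f$n, numeric(1)) == t1$n))
  # with no fiber effect there is no confounding path. Percent change is
  # only well-scaled for the analyte with a real effect (PFOA here); for
  # the null analytes check the absolute coefficient shift instead
  for (ft in c("total", "soluble")) {
    expect_lt(abs(t1$assessments[[paste0("PFOA.", ft)]]$percent_change), 8)
    for (an in c("PFOS", "PFNA")) {
      d_abs <- abs(t1$fits[[paste(an, "none", sep = ".")]]$coefficients[["x"]] -
                     t1$fits[[paste(an, ft, sep = ".")]]$coefficients[["x"]])
      expect_lt(d_abs, 3e-4)
    }
  }
})

test_that("naive OLS on generated data converges to the attenuation identities", {
  p <- tiny_params() # omega2 0.04, tau2 0.08 -> lambda = 0.5
  en <- expected_naive_bias(p)
  expect_equal(en$lambda, 0.5)
  b <- sim_bundle(p, 50000, seed = 77)
  fit <- fit_ols(b, include_fiber = TRUE)
  expect_lt(abs(fit$coefficients[["f_bar"]] - en$fiber_slope),
            3 * fit$standard_errors[["f_bar"]])
  expect_lt(abs(fit$coefficients[["x"]] - en$pfas_slope),
            3 * fit$standard_errors[["x"]])
})
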