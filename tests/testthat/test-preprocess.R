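# preprocessing: isomer sums, LOD imputation, energy adjustment,
# shift-log transform, fiber replicates, exclusion cascade

test_that("isomer summation fills totals and passes complete rows through", {
  rec <- fixture_records(5)
  rec$pfoa_linear <- c(2.0, 1.5, NA, 0, 4.1)
  rec$pfoa_branched <- c(0.5, 0.2, NA, 0, 0.9)
  truth <- rec$pfoa
  rec$pfoa[c(1, 4)] <- NA # waves with separate isomers lack the total
  out <- sum_isomers(rec)
  expect_equal(out$pfoa[1], 2.5)
  expect_equal(out$pfoa[4], 0)
  expect_equal(out$pfoa[-c(1, 4)], truth[-c(1, 4)]) # pass-through unchanged
  # one isomer present, the other missing -> input error
  rec$pfoa[2] <- NA
  rec$pfoa_branched[2] <- NA
  expect_error(sum_isomers(rec), "isomer")
})

test_that("below-LOD values are imputed as LOD/sqrt(2)", {
  expect_equal(impute_lod(NA_real_, lod = 0.1), 0.1 / sqrt(2))
  expect_equal(impute_lod(3.2, lod = 0.1), 3.2)
  expect_error(impute_lod(1, lod = 0), "lod")
  # simulated batch: exactly the flagged fraction ends up at LOD/sqrt(2)
  set.seed(1)
  v <- rlnorm(1000, 0, 0.5)
  below <- v < quantile(v, 0.01)
  v[below] <- NA
  out <- impute_lod(v, lod = 0.2)
  expect_equal(sum(out == 0.2 / sqrt(2)), sum(below))
  expect_equal(out[!below], v[!below])
})

test_that("energy adjustment equals the least-squares residual and is orthogonal to energy", {
  # exact linear relation -> all residuals zero
  energy <- c(1500, 2000, 2500, 3000)
  expect_equal(energy_adjust(5 + 0.004 * energy, energy), rep(0, 4))
  # constant energy -> mean-centering fallback with a warning
  expect_warning(
    res <- energy_adjust(c(10, 20, 30), c(2000, 2000, 2000)),
    "zero variance")
  expect_equal(res, c(-10, 0, 10))
  # random fixture matches an explicit normal-equations solve
  set.seed(4)
  e <- runif(20, 1200, 3200)
  f <- 3 + 0.005 * e + rnorm(20, 0, 3)
  res <- energy_adjust(f, e)
  X <- cbind(1, e)
  beta <- solve(t(X) %*% X, t(X) %*% f)
  expect_equal(res, as.numeric(f - X %*% beta), tolerance = 1e-10)
  expect_equal(sum(res), 0, tolerance = 1e-8)
  expect_equal(sum(res * e), 0, tolerance = 1e-6) # orthogonality
})

test_that("shift-log transforms and flags its domain boundary", {
  expect_equal(as.numeric(shift_log(0)), log(40))
  expect_equal(as.numeric(shift_log(-39)), 0)
  out <- shift_log(c(-40, -41, 2))
  expect_true(all(is.na(out[1:2])))
  expect_equal(attr(out, "flagged"), c(1L, 2L))
  expect_equal(out[3], log(42))
})

test_that("fiber replicates collapse when the two days are identical", {
  rec <- fixture_records(12)
  rec$soluble_fiber_d2 <- rec$soluble_fiber_d1
  rec$energy_d2 <- rec$energy_d1
  fv <- build_fiber_variables(rec, "soluble")
  expect_equal(fv$f_star_1, fv$f_star_2)
  expect_equal(fv$f_bar, fv$f_star_1)
})

test_that("replicate-difference variance recovers the generating tau2", {
  tau2 <- 0.0035
  d <- generate_synthetic(8000, seed = 31)
  fv <- build_fiber_variables(d$records, "soluble")
  est <- var(fv$f_star_1 - fv$f_star_2, na.rm = TRUE) / 2
  # moment identity Var(F1* - F2*)/2 = tau2; MC standard error of a
  # variance of n iid gaussians is var * sqrt(2/n)
  mc_se <- tau2 * sqrt(2 / sum(!is.na(fv$f_star_1)))
  expect_lt(abs(est - tau2), 4 * mc_se + 0.1 * tau2)
  # tau2 = 0 data: replicates coincide up to the raw-scale floor
  p0 <- default_parameters()
  p0$tau2 <- 0
  d0 <- generate_synthetic(500, params = p0, seed = 32)
  fv0 <- build_fiber_variables(d0$records, "soluble")
  # the two day-specific adjustment regressions differ only by estimation
  # noise, so the replicate difference is tiny but not exactly zero
  expect_lt(var(fv0$f_star_1 - fv0$f_star_2), 5e-4)
  expect_lt(var(d0$f_star[, 1] - d0$f_star[, 2]), 1e-20)
})

test_that("fiber-variable construction is equivariant under row permutation", {
  rec <- fixture_records(15)
  fv <- build_fiber_variables(rec, "total")
  perm <- sample(15)
  fv_p <- build_fiber_variables(rec[perm, ], "total")
  expect_equal(fv_p$f_star_1, fv$f_star_1[perm])
  expect_equal(fv_p$f_bar, fv$f_bar[perm])
})

test_that("exclusion cascade drops medication users then z-outliers, once", {
  d <- generate_synthetic(100, seed = 8)
  rec <- d$records
  rec$on_chol_medication[c(3, 7)] <- TRUE
  # plant a gross cholesterol outlier (far beyond 2.57 SD of ln scale)
  rec$cholesterol[10] <- exp(mean(log(rec$cholesterol)) +
                               8 * sd(log(rec$cholesterol)))
  out <- apply_exclusions(rec)
  expect_equal(out$report$n_input, 100L)
  expect_equal(out$report$n_after_medication, 98L)
  expect_equal(sort(out$report$excluded$medication), c(3L, 7L))
  expect_true(10L %in% out$report$excluded$outlier)
  # id lists are disjoint, counts non-increasing
  all_ids <- unlist(out$report$excluded)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_true(out$report$n_after_outlier <= out$report$n_after_medication)
  # brute-force z-score check of the cholesterol rule on the post-med sample
  post_med <- rec[!(rec$subject_id %in% c(3, 7)), ]
  z <- scale(log(post_med$cholesterol))
  expect_true(all(post_med$subject_id[abs(z) > 2.57] %in%
                    out$report$excluded$outlier))
})

test_that("identical values produce no outliers (zero-SD guard)", {
  rec <- fixture_records(8)
  rec$cholesterol[] <- 180
  rec$total_fiber_d1[] <- 15; rec$total_fiber_d2[] <- 15
  rec$soluble_fiber_d1[] <- 5; rec$soluble_fiber_d2[] <- 5
  rec$energy_d1[] <- 2000; rec$energy_d2[] <- 2000
  out <- suppressWarnings(apply_exclusions(rec))
  expect_equal(out$report$n_after_outlier, 8L)
  expect_length(out$report$excluded$outlier, 0L)
})

test_that("re-applying the exclusion rule to retained records removes under 1%", {
  d <- generate_synthetic(4000, seed = 9)
  once <- apply_exclusions(d$records)
  twice <- apply_exclusions(once$records)
  removed_again <- once$report$n_after_outlier - twice$report$n_after_outlier
  expect_lt(removed_again / once$report$n_after_outlier, 0.01)
})
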