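# OLS reference analysis: ln(cholesterol) regressions, change-in-estimate
# confounding criterion, quadratic-term AIC sensitivity check

#' Fit one ln(cholesterol) regression by ordinary least squares
#'
#' Regresses `y = ln(cholesterol)` on the PFAS analyte, optionally the
#' averaged transformed fiber variable `f_bar`, and all encoded covariates.
#' Standard errors are the conventional OLS ones. The AIC uses the full
#' Gaussian log-likelihood (variance parameter counted, constants
#' retained), so differences are comparable across nested fits.
#'
#' @param bundle A [design_bundle()].
#' @param include_fiber Add `f_bar` to the design? Requires fiber
#'   replicates in the bundle.
#' @return An object of class `ols_fit`: named `coefficients` and
#'   `standard_errors`, `n`, `aic`, `residual_variance` (RSS / (n - p)),
#'   `loglik`, and `rss`.
#' @export
fit_ols <- function(bundle, include_fiber = !is.null(bundle$f_star_1)) {
  stopifnot(inherits(bundle, "design_bundle"))
  if (include_fiber && is.null(bundle$f_bar)) {
    stop("bundle has no fiber replicates; cannot include fiber", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x = bundle$x,
             if (include_fiber) cbind(f_bar = bundle$f_bar),
             bundle$c)
  ols_solve(X, bundle$y)
}

# core least-squares with rank checking, shared by fit_ols and the
# quadratic sensitivity fit
ols_solve <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (n <= p + 1L) stop("need n > number of terms + 1", call. = FALSE)
  coef <- qr.coef(qr_x, y)
  resid <- y - drop(X %*% coef)
  rss <- sum(resid^2)
  s2 <- rss / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(XtX_inv))
  names(se) <- names(coef)
  # Gaussian log-likelihood at the MLE variance rss/n; k counts sigma^2
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  aic <- 2 * (p + 1) - 2 * loglik
  structure(
    list(coefficients = coef, standard_errors = se, n = n, aic = aic,
         residual_variance = s2, loglik = loglik, rss = rss),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, %d terms, AIC = %.2f\n",
              x$n, length(x$coefficients), x$aic))
  show <- intersect(c("x", "f_bar"), names(x$coefficients))
  for (nm in show) {
    cat(sprintf("  %-6s %12.5g (SE %.5g)\n", nm, x$coefficients[[nm]],
                x$standard_errors[[nm]]))
  }
  invisible(x)
}

#' Change-in-estimate confounding assessment
#'
#' Computes the percent change in the PFAS coefficient between the
#' fiber-unadjusted and fiber-adjusted fits,
#' `100 * (b_unadjusted - b_adjusted) / b_unadjusted` (positive values mean
#' the coefficient shrank after adjustment), and flags confounding when the
#' absolute change reaches 10%.
#'
#' @param fit_without,fit_with Two fits (class `ols_fit`, or any object
#'   whose `coefficients` element carries `pfas_term`) on the same sample.
#' @param pfas_term Name of the PFAS coefficient, default `"x"`.
#' @param threshold Percent-change threshold for flagging, default 10.
#' @return An object of class `confounding_assessment` with
#'   `beta_unadjusted`, `beta_adjusted`, `percent_change`, `flagged`.
#' @export
#' @examples
#' f1 <- list(coefficients = c(x = 2.59e-3), n = 10)
#' f2 <- list(coefficients = c(x = 2.45e-3), n = 10)
#' assess_confounding(f1, f2)$percent_change # 5.4
assess_confounding <- function(fit_without, fit_with, pfas_term = "x",
                               threshold = 10) {
  b0 <- fit_without$coefficients[[pfas_term]]
  b1 <- fit_with$coefficients[[pfas_term]]
  if (is.null(b0) || is.null(b1)) {
    stop("PFAS term '", pfas_term, "' not found in both fits", call. = FALSE)
  }
  if (!is.null(fit_without$n) && !is.null(fit_with$n) &&
      fit_without$n != fit_with$n) {
    stop("fits are on different samples (n = ", fit_without$n, " vs ",
         fit_with$n, ")", call. = FALSE)
  }
  if (b0 == 0) {
    stop("unadjusted coefficient is zero; percent change undefined",
         call. = FALSE)
  }
  pct <- 100 * (b0 - b1) / b0
  structure(
    list(beta_unadjusted = b0, beta_adjusted = b1, percent_change = pct,
         flagged = abs(pct) >= threshold, threshold = threshold),
    class = "confounding_assessment"
  )
}

#' @export
print.confounding_assessment <- function(x, ...) {
  cat(sprintf(
    "Change-in-estimate: %.4g -> %.4g (%.1f%% change); confounding %s (>= %g%% rule)\n",
    x$beta_unadjusted, x$beta_adjusted, x$percent_change,
    if (x$flagged) "FLAGGED" else "not flagged", x$threshold))
  invisible(x)
}

#' Quadratic-PFAS sensitivity check
#'
#' Refits the model with an added quadratic PFAS term, the square of the
#' centered analyte, and compares Akaike Information Criterion values.
#' `delta_aic = aic_linear - aic_quadratic`, so positive values favor the
#' quadratic model.
#'
#' @param bundle A [design_bundle()].
#' @param include_fiber Passed to [fit_ols()].
#' @return A list: `linear` and `quadratic` fits, and `delta_aic`.
#' @export
quadratic_sensitivity <- function(bundle,
                                  include_fiber = !is.null(bundle$f_star_1)) {
  fit_lin <- fit_ols(bundle, include_fiber)
  xc <- bundle$x - mean(bundle$x)
  X <- cbind(`(Intercept)` = 1, x = bundle$x, x2 = xc^2,
             if (include_fiber) cbind(f_bar = bundle$f_bar),
             bundle$c)
  fit_quad <- ols_solve(X, bundle$y)
  list(linear = fit_lin, quadratic = fit_quad,
       delta_aic = fit_lin$aic - fit_quad$aic)
}

#' Fit the full three-by-three OLS model grid
#'
#' Applies the exclusion cascade once, then fits ln(cholesterol) on each of
#' the three PFAS analytes under each fiber setting (`none`, `total`,
#' `soluble`), all on the common retained sample, together with the
#' change-in-estimate assessment of each fiber-adjusted model against its
#' unadjusted counterpart.
#'
#' @param records A [subject_records()] data.frame (pre-exclusion).
#' @param config An [analysis_config()]; its `pfas_analyte`/`fiber_type`
#'   are ignored here because the grid spans all of them.
#' @return An object of class `table1_fits`: a list with `fits` (named
#'   `"<ANALYTE>.<fiber>"`), `assessments`, `n`, and `exclusions`.
#' @export
run_table1 <- function(records, config = analysis_config()) {
  ex <- apply_exclusions(records, config)
  r <- ex$records
  if (nrow(r) == 0L) stop("no records retained after exclusions",
                          call. = FALSE)
  fits <- list()
  assessments <- list()
  for (analyte in c("PFOA", "PFOS", "PFNA")) {
    for (ft in c("none", "total", "soluble")) {
      cfg <- config
      cfg$pfas_analyte <- analyte
      cfg$fiber_type <- ft
      bundle <- build_design_bundle(r, cfg)
      fits[[paste(analyte, ft, sep = ".")]] <-
        fit_ols(bundle, include_fiber = ft != "none")
    }
    for (ft in c("total", "soluble")) {
      assessments[[paste(analyte, ft, sep = ".")]] <- assess_confounding(
        fits[[paste(analyte, "none", sep = ".")]],
        fits[[paste(analyte, ft, sep = ".")]]
      )
    }
  }
  structure(
    list(fits = fits, assessments = assessments, n = nrow(r),
         exclusions = ex$report),
    class = "table1_fits"
  )
}

#' @export
print.table1_fits <- function(x, ...) {
  cat(sprintf("OLS model grid (3 analytes x 3 fiber settings), n = %d\n", x$n))
  for (nm in names(x$assessments)) {
    a <- x$assessments[[nm]]
    cat(sprintf("  %-14s PFAS coef change %+.1f%%%s\n", nm,
                a$percent_change, if (a$flagged) "  [>=10%: confounding]" else ""))
  }
  invisible(x)
}
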