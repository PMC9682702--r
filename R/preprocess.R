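# preprocessing: raw records -> analysis variables

#' Sum linear and branched PFAS isomers
#'
#' In the survey cycles where linear and branched isomers of PFOA and PFOS
#' were assayed separately, the analysis uses their sum. Rows that already
#' carry a total pass through unchanged; rows with isomer columns get
#' `pfoa = pfoa_linear + pfoa_branched` (and likewise for PFOS).
#'
#' @param records A [subject_records()] data.frame.
#' @return The records with `pfoa` and `pfos` totals filled in.
#' @export
sum_isomers <- function(records) {
  stopifnot(is.data.frame(records))
  for (analyte in c("pfoa", "pfos")) {
    lin_col <- paste0(analyte, "_linear")
    br_col <- paste0(analyte, "_branched")
    if (!all(c(lin_col, br_col) %in% names(records))) next
    lin <- records[[lin_col]]
    br <- records[[br_col]]
    need <- is.na(records[[analyte]])
    half <- need & (is.na(lin) != is.na(br))
    if (any(half)) {
      stop(sprintf("input error: row(s) %s have one %s isomer but not the other",
                   paste(utils::head(which(half), 5L), collapse = ", "),
                   toupper(analyte)), call. = FALSE)
    }
    fill <- need & !is.na(lin) & !is.na(br)
    records[[analyte]][fill] <- lin[fill] + br[fill]
  }
  records
}

#' Impute values below the limit of detection
#'
#' Applies the standard convention for left-censored assay values: a
#' measurement below the limit of detection (LOD) is replaced by
#' `lod / sqrt(2)`. Detected values are returned unchanged. Real analytic
#' files arrive with this imputation already applied by the data provider;
#' the function exists so the synthetic generator can emulate the
#' convention.
#'
#' @param values Numeric vector of concentrations (ng/mL); `NA` marks a
#'   below-LOD observation unless `below` is supplied.
#' @param lod Limit of detection, ng/mL (> 0).
#' @param below Logical vector flagging below-LOD entries; defaults to
#'   `is.na(values)`.
#' @return Numeric vector with below-LOD entries set to `lod / sqrt(2)`.
#' @export
#' @examples
#' impute_lod(c(NA, 3.2), lod = 0.1) # 0.0707..., 3.2
impute_lod <- function(values, lod, below = is.na(values)) {
  if (!is.numeric(lod) || length(lod) != 1L || !is.finite(lod) || lod <= 0) {
    stop("input error: `lod` must be a single value > 0", call. = FALSE)
  }
  stopifnot(length(below) == length(values))
  values[below] <- lod / sqrt(2)
  values
}

#' Energy-adjust nutrient intake by the residual method
#'
#' Replaces a nutrient intake with its residual from an ordinary
#' least-squares regression on total energy intake, so the adjusted variable
#' reflects diet composition rather than the amount eaten. Residuals sum to
#' zero and are orthogonal to energy by construction.
#'
#' @param fiber Numeric vector, nutrient intake (g/d).
#' @param energy Numeric vector, energy intake (kcal/d), same length,
#'   `n >= 3`.
#' @return Residual vector (g/d). If energy has zero variance the regression
#'   is degenerate and the fallback `fiber - mean(fiber)` is returned with a
#'   warning.
#' @export
energy_adjust <- function(fiber, energy) {
  n <- length(fiber)
  if (length(energy) != n) stop("vectors must share one length", call. = FALSE)
  if (n < 3L) stop("need n >= 3 for the adjustment regression", call. = FALSE)
  if (anyNA(fiber) || anyNA(energy)) {
    stop("energy adjustment requires complete intake data", call. = FALSE)
  }
  if (stats::var(energy) == 0) {
    warning("energy intake has zero variance; falling back to mean-centering",
            call. = FALSE)
    return(fiber - mean(fiber))
  }
  fit <- stats::lm.fit(cbind(1, energy), fiber)
  unname(fit$residuals)
}

#' Shift-log transform of energy-adjusted fiber
#'
#' Energy-adjusted residuals can be negative, so a fixed shift (default
#' 40 g/d) is added before taking the natural log. Values whose shifted
#' argument is not positive are flagged for exclusion (returned as `NA` and
#' listed in the `"flagged"` attribute), never silently clipped.
#'
#' @param residual Numeric vector of energy-adjusted fiber (g/d).
#' @param shift Shift in g/d (> 0), default 40.
#' @return `ln(residual + shift)` with attribute `flagged`: the integer
#'   indices where `residual + shift <= 0`.
#' @export
#' @examples
#' shift_log(0)    # log(40)
#' shift_log(-39)  # 0
shift_log <- function(residual, shift = 40) {
  if (!is.numeric(shift) || shift <= 0) stop("`shift` must be > 0",
                                             call. = FALSE)
  arg <- residual + shift
  bad <- which(!is.na(arg) & arg <= 0)
  out <- rep(NA_real_, length(arg))
  ok <- !is.na(arg) & arg > 0
  out[ok] <- log(arg[ok])
  attr(out, "flagged") <- bad
  out
}

#' Build the transformed fiber replicates and their average
#'
#' For each recall day separately: energy-adjust the day's fiber on the
#' day's energy (two day-specific regressions over the full sample), add
#' the shift, take the natural log. The two transformed days are the
#' replicate measurements `F1*`, `F2*` of latent long-term intake; their
#' average on the ln scale, `f_bar`, is the observed-fiber variable of the
#' OLS analysis.
#'
#' @param records A [subject_records()] data.frame with two complete recall
#'   days.
#' @param fiber_type `"total"` or `"soluble"`.
#' @param shift Shift in g/d before the log, default 40.
#' @return A list with `f_star_1`, `f_star_2`, `f_bar` (each length
#'   `nrow(records)`, `NA` where flagged) and `flagged`, the row indices
#'   excluded by the shift-log domain rule.
#' @export
build_fiber_variables <- function(records, fiber_type = c("soluble", "total"),
                                  shift = 40) {
  fiber_type <- match.arg(fiber_type)
  col <- paste0(fiber_type, "_fiber_d")
  res1 <- energy_adjust(records[[paste0(col, 1L)]], records$energy_d1)
  res2 <- energy_adjust(records[[paste0(col, 2L)]], records$energy_d2)
  f1 <- shift_log(res1, shift)
  f2 <- shift_log(res2, shift)
  flagged <- sort(union(attr(f1, "flagged"), attr(f2, "flagged")))
  f1 <- as.numeric(f1)
  f2 <- as.numeric(f2)
  list(f_star_1 = f1, f_star_2 = f2, f_bar = (f1 + f2) / 2, flagged = flagged)
}

# columns that must be observed for a subject to be analyzable
.complete_case_cols <- c("pfoa", "pfos", "pfna", "cholesterol",
                         "energy_d1", "energy_d2",
                         "total_fiber_d1", "total_fiber_d2",
                         "soluble_fiber_d1", "soluble_fiber_d2",
                         "age", "sex", "race_ethnicity",
                         "income_poverty_ratio", "smoking", "sat_fat",
                         "diet_cholesterol", "wave")

#' Apply the exclusion cascade
#'
#' Reproduces the analytic-sample definition: (0) complete-case filtering on
#' every analysis variable, (1) removal of subjects reporting
#' cholesterol-lowering medication (bile-acid sequestrants, ezetimibe,
#' orlistat, statins, or combination therapy), then (2) removal of outliers,
#' defined as `|z| > outlier_z` (default 2.57, the 99th-percentile band of
#' the normal distribution) for ln-transformed shifted energy-adjusted fiber
#' or ln-transformed cholesterol, with mean and SD computed on the
#' post-medication-exclusion sample. The rule is applied exactly once.
#'
#' So that the fiber-free, total-fiber, and soluble-fiber models all share
#' one sample size, the outlier screen always uses ln(cholesterol) together
#' with both fiber variables (the intersection sample).
#'
#' @param records A [subject_records()] data.frame.
#' @param config An [analysis_config()]; `shift_gd` and `outlier_z` are
#'   used.
#' @return A list: `records` (the retained subset) and `report`, an
#'   `exclusion_report` with counts and per-rule excluded subject ids.
#' @export
apply_exclusions <- function(records, config = analysis_config()) {
  stopifnot(inherits(records, "subject_records"))
  n_input <- nrow(records)

  cc <- stats::complete.cases(records[, .complete_case_cols])
  excl_incomplete <- records$subject_id[!cc]
  r <- records[cc, , drop = FALSE]

  med <- r$on_chol_medication %in% TRUE
  excl_medication <- r$subject_id[med]
  r <- r[!med, , drop = FALSE]
  n_after_medication <- nrow(r)

  # outlier screen on the post-medication sample
  z_out <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) return(rep(FALSE, length(v)))
    abs((v - mean(v)) / s) > config$outlier_z
  }
  out <- rep(FALSE, nrow(r))
  domain_flagged <- integer(0)
  if (nrow(r) > 0) {
    lnchol <- log(r$cholesterol)
    out <- z_out(lnchol)
    for (ft in c("total", "soluble")) {
      fv <- build_fiber_variables(r, ft, shift = config$shift_gd)
      domain_flagged <- union(domain_flagged, fv$flagged)
      ok <- !is.na(fv$f_bar)
      z <- rep(FALSE, nrow(r))
      s <- stats::sd(fv$f_bar[ok])
      if (!is.na(s) && s > 0) {
        z[ok] <- abs((fv$f_bar[ok] - mean(fv$f_bar[ok])) / s) > config$outlier_z
      }
      out <- out | z
    }
    out[domain_flagged] <- TRUE
  }
  excl_outlier <- r$subject_id[out]
  r <- r[!out, , drop = FALSE]
  n_after_outlier <- nrow(r)

  report <- structure(
    list(n_input = n_input,
         n_after_medication = n_after_medication,
         n_after_outlier = n_after_outlier,
         excluded = list(incomplete = excl_incomplete,
                         medication = excl_medication,
                         outlier = excl_outlier),
         empty_result = n_after_outlier == 0L),
    class = "exclusion_report"
  )
  list(records = r, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade\n")
  cat(sprintf("  input records:            %d\n", x$n_input))
  cat(sprintf("  incomplete data:         -%d\n", length(x$excluded$incomplete)))
  cat(sprintf("  cholesterol medication:  -%d  (n = %d)\n",
              length(x$excluded$medication), x$n_after_medication))
  cat(sprintf("  outliers (|z| screen):   -%d  (n = %d)\n",
              length(x$excluded$outlier), x$n_after_outlier))
  if (x$empty_result) cat("  WARNING: no records retained\n")
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report An `exclusion_report`.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
exclusion_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "exclusion_report"))
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Build the full design bundle for one analysis
#'
#' Convenience wrapper: runs [build_fiber_variables()] (unless
#' `fiber_type = "none"`), [encode_covariates()], and assembles the
#' [design_bundle()] for the configured analyte on already-filtered records.
#'
#' @param records Retained [subject_records()] (post-exclusion, complete).
#' @param config An [analysis_config()].
#' @return A [design_bundle()].
#' @export
build_design_bundle <- function(records, config = analysis_config()) {
  x <- records[[tolower(config$pfas_analyte)]]
  y <- log(records$cholesterol)
  cmat <- encode_covariates(records, include_bmi = config$include_bmi)
  if (config$fiber_type == "none") {
    return(design_bundle(y = y, x = x, c = cmat))
  }
  fv <- build_fiber_variables(records, config$fiber_type,
                              shift = config$shift_gd)
  if (length(fv$flagged)) {
    stop("shift-log domain violations remain after exclusions; rows: ",
         paste(utils::head(fv$flagged, 5L), collapse = ", "), call. = FALSE)
  }
  design_bundle(y = y, x = x, f_star_1 = fv$f_star_1,
                f_star_2 = fv$f_star_2, c = cmat)
}
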