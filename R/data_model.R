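#' @keywords internal
"_PACKAGE"

# canonical analytic-file schema ------------------------------------------

# required numeric columns of the analytic dataset
.numeric_cols <- c(
  "pfoa", "pfos", "pfna", "cholesterol",
  "energy_d1", "energy_d2",
  "total_fiber_d1", "total_fiber_d2",
  "soluble_fiber_d1", "soluble_fiber_d2",
  "age", "income_poverty_ratio", "sat_fat", "diet_cholesterol"
)
.integer_cols <- c("smoking", "wave")
.category_cols <- c("sex", "race_ethnicity")
# optional: isomer concentrations (waves where linear/branched are separate),
# medication flag, body mass index
.optional_numeric_cols <- c("pfoa_linear", "pfoa_branched",
                            "pfos_linear", "pfos_branched", "bmi")

.required_cols <- c(.numeric_cols, .integer_cols, .category_cols)

.nonneg_cols <- c("pfoa", "pfos", "pfna", "cholesterol",
                  "energy_d1", "energy_d2",
                  "total_fiber_d1", "total_fiber_d2",
                  "soluble_fiber_d1", "soluble_fiber_d2",
                  "sat_fat", "diet_cholesterol",
                  .optional_numeric_cols)

#' Construct a validated collection of subject records
#'
#' One row per subject with serum PFAS concentrations (PFOA, PFOS, PFNA;
#' ng/mL), serum total cholesterol (mg/dL), two days of 24-hour dietary
#' recall (energy in kcal/d; total and soluble fiber in g/d), and the
#' secondary covariates used in the regression models. Missing values are
#' allowed (complete-case handling happens in the exclusion cascade), but
#' concentrations and intakes must be non-negative where present, smoking
#' must be an ordinal code in 0..3, and wave a positive integer survey-cycle
#' index.
#'
#' @param df A data.frame holding the canonical columns (see
#'   [analytic_columns()]). A `subject_id` column is added from the row
#'   number when absent, and a logical `on_chol_medication` column defaults
#'   to `FALSE` when absent.
#'
#' @return The validated data.frame with class `subject_records`.
#' @export
subject_records <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- seq_len(nrow(df))
  if (!"on_chol_medication" %in% names(df)) df$on_chol_medication <- FALSE
  df$on_chol_medication <- as.logical(df$on_chol_medication)

  for (col in intersect(.nonneg_cols, names(df))) {
    bad <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(bad)) {
      stop(sprintf("column '%s' has %d negative value(s); concentrations and intakes must be >= 0",
                   col, sum(bad)), call. = FALSE)
    }
  }
  smk <- df$smoking[!is.na(df$smoking)]
  if (length(smk) && !all(smk %in% 0:3)) {
    stop("'smoking' must be an ordinal code in {0, 1, 2, 3}", call. = FALSE)
  }
  wv <- df$wave[!is.na(df$wave)]
  if (length(wv) && (any(wv != round(wv)) || any(wv < 1))) {
    stop("'wave' must be a positive integer survey-cycle index", call. = FALSE)
  }
  n_race <- length(unique(df$race_ethnicity[!is.na(df$race_ethnicity)]))
  if (n_race > 5L) {
    stop("'race_ethnicity' must have at most 5 levels, found ", n_race,
         call. = FALSE)
  }
  class(df) <- c("subject_records", "data.frame")
  df
}

#' Canonical column names of the analytic dataset
#'
#' @return A list with elements `required`, `optional`, `numeric`,
#'   `integer`, and `categorical`.
#' @export
analytic_columns <- function() {
  list(
    required = .required_cols,
    optional = c("subject_id", "on_chol_medication", .optional_numeric_cols),
    numeric = c(.numeric_cols, .optional_numeric_cols),
    integer = .integer_cols,
    categorical = .category_cols
  )
}

# parse a character vector to numeric; unparseable cells become NA silently
.parse_num <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "na", ".", "NaN")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read an analytic CSV into subject records
#'
#' Reads a one-row-per-subject CSV (RFC-4180, header row). Column names in
#' the file may differ from the canonical names; a two-column dictionary
#' (`canonical_name`, `file_name`) maps them. Unparseable numeric cells
#' become explicit `NA`, never silent zeros, and row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param dictionary Optional column-name map: either a data.frame with
#'   columns `canonical_name` and `file_name`, or the path of a two-column
#'   CSV holding them.
#'
#' @return A [subject_records()] data.frame.
#' @export
read_analytic_csv <- function(path, dictionary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("input error: empty analytic file: ", path,
                            call. = FALSE)
  if (!is.null(dictionary)) {
    if (is.character(dictionary) && length(dictionary) == 1L) {
      dictionary <- utils::read.csv(dictionary, stringsAsFactors = FALSE)
    }
    if (!all(c("canonical_name", "file_name") %in% names(dictionary))) {
      stop("dictionary must have columns 'canonical_name' and 'file_name'",
           call. = FALSE)
    }
    hit <- match(names(raw), dictionary$file_name)
    names(raw)[!is.na(hit)] <- dictionary$canonical_name[hit[!is.na(hit)]]
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop("configuration error: required column(s) not resolvable: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw
  for (col in intersect(c(.numeric_cols, .integer_cols,
                          .optional_numeric_cols), names(out))) {
    out[[col]] <- .parse_num(out[[col]])
  }
  for (col in .integer_cols) out[[col]] <- as.integer(out[[col]])
  if ("on_chol_medication" %in% names(out)) {
    out$on_chol_medication <-
      tolower(trimws(out$on_chol_medication)) %in% c("1", "true", "t", "yes")
  }
  subject_records(out)
}

#' Write subject records to an analytic CSV
#'
#' Inverse of [read_analytic_csv()]: `read(write(x))` is the identity on the
#' canonical columns.
#'
#' @param records A [subject_records()] data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analytic_csv <- function(records, path) {
  stopifnot(inherits(records, "subject_records"))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

# covariate encoding ------------------------------------------------------

#' Encode secondary covariates into a centered design block
#'
#' Builds the covariate matrix `C` shared by the OLS, maximum-likelihood,
#' and Bayesian models: continuous covariates (two-day mean energy intake,
#' saturated fat, dietary cholesterol, age, income-to-poverty ratio) are
#' mean-centered; sex becomes a single indicator against a reference level;
#' race/ethnicity becomes four indicators against a reference level; smoking
#' stays a single ordinal numeric column; and the survey wave enters as a
#' centered linear term plus the square of that centered term.
#'
#' @param records A [subject_records()] data.frame with no missing covariate
#'   values.
#' @param reference_levels Named list choosing the reference category for
#'   `sex` and `race_ethnicity`; defaults to the most frequent level of each.
#' @param include_bmi If `TRUE`, a centered `bmi` column is appended
#'   (requires a `bmi` column in `records`). Default `FALSE`: the fitted
#'   covariate set matches the reported regression models, which did not
#'   include body mass index.
#'
#' @return A numeric matrix with named columns; attributes `centers` (the
#'   subtracted means) and `reference_levels` record the encoding so it can
#'   be reapplied.
#' @export
encode_covariates <- function(records, reference_levels = list(),
                              include_bmi = FALSE) {
  stopifnot(is.data.frame(records))
  cont <- c("age", "income_poverty_ratio", "sat_fat", "diet_cholesterol")
  need <- c(cont, "energy_d1", "energy_d2", "sex", "race_ethnicity",
            "smoking", "wave", if (include_bmi) "bmi")
  for (col in need) {
    if (!col %in% names(records)) {
      stop("covariate column missing: ", col, call. = FALSE)
    }
    if (anyNA(records[[col]])) {
      stop("missing values in covariate '", col,
           "'; apply complete-case filtering first", call. = FALSE)
    }
  }
  n <- nrow(records)
  centers <- c()
  out <- list()

  center <- function(x, name) {
    m <- mean(x)
    centers[[name]] <<- m
    x - m
  }

  out$energy <- center((records$energy_d1 + records$energy_d2) / 2, "energy")
  out$sat_fat <- center(records$sat_fat, "sat_fat")
  out$diet_cholesterol <- center(records$diet_cholesterol, "diet_cholesterol")
  out$age <- center(records$age, "age")
  out$income_poverty_ratio <- center(records$income_poverty_ratio,
                                     "income_poverty_ratio")
  if (include_bmi) out$bmi <- center(records$bmi, "bmi")

  ref <- function(var, levels_seen) {
    r <- reference_levels[[var]]
    if (is.null(r)) {
      r <- names(sort(table(records[[var]]), decreasing = TRUE))[1L]
    } else if (!r %in% levels_seen) {
      stop("reference level '", r, "' not present in '", var, "'",
           call. = FALSE)
    }
    r
  }

  sex_levels <- sort(unique(as.character(records$sex)))
  if (length(sex_levels) > 2L) {
    stop("input error: 'sex' must be binary; unseen levels: ",
         paste(sex_levels, collapse = ", "), call. = FALSE)
  }
  sex_ref <- ref("sex", sex_levels)
  refs <- list(sex = sex_ref)
  for (lev in setdiff(sex_levels, sex_ref)) {
    out[[paste0("sex_", lev)]] <- as.numeric(records$sex == lev)
  }

  race_levels <- sort(unique(as.character(records$race_ethnicity)))
  if (length(race_levels) > 5L) {
    stop("input error: unseen race/ethnicity level(s): ",
         paste(race_levels, collapse = ", "), call. = FALSE)
  }
  race_ref <- ref("race_ethnicity", race_levels)
  refs$race_ethnicity <- race_ref
  for (lev in setdiff(race_levels, race_ref)) {
    out[[paste0("race_", lev)]] <- as.numeric(records$race_ethnicity == lev)
  }

  out$smoking <- as.numeric(records$smoking)
  wave_c <- center(as.numeric(records$wave), "wave")
  out$wave <- wave_c
  out$wave2 <- wave_c^2

  m <- do.call(cbind, out)
  rownames(m) <- NULL
  structure(m, centers = unlist(centers), reference_levels = refs)
}

# design bundle -----------------------------------------------------------

#' Assemble the observables of one analysis
#'
#' Bundles the outcome vector `y = ln(cholesterol)`, one PFAS analyte `x`
#' (ng/mL, untransformed), the two transformed fiber replicates
#' `f_star_1`, `f_star_2` and their average `f_bar` (all on the
#' ln(shifted energy-adjusted g/d) scale), and the encoded covariate matrix
#' `c`.
#'
#' @param y Numeric vector, ln(serum total cholesterol).
#' @param x Numeric vector, serum PFAS concentration (ng/mL).
#' @param f_star_1,f_star_2 Transformed replicate fiber measurements; may be
#'   `NULL` for a fiber-free analysis.
#' @param c Numeric covariate matrix from [encode_covariates()] (may have
#'   zero columns).
#'
#' @return An object of class `design_bundle`.
#' @export
design_bundle <- function(y, x, f_star_1 = NULL, f_star_2 = NULL,
                          c = matrix(numeric(0), length(y), 0)) {
  n <- length(y)
  c <- as.matrix(c)
  has_fiber <- !is.null(f_star_1)
  if (has_fiber && is.null(f_star_2)) {
    stop("both fiber replicates are required when one is given", call. = FALSE)
  }
  lens <- base::c(length(x),
                  if (has_fiber) base::c(length(f_star_1), length(f_star_2)),
                  nrow(c))
  if (any(lens != n)) {
    stop("all bundle components must share one length n = ", n, call. = FALSE)
  }
  if (anyNA(y) || anyNA(x) || anyNA(c) ||
      (has_fiber && (anyNA(f_star_1) || anyNA(f_star_2)))) {
    stop("bundle components must be complete (no missing values)",
         call. = FALSE)
  }
  if (ncol(c) > 0 && is.null(colnames(c))) {
    stop("covariate matrix must have named columns", call. = FALSE)
  }
  structure(
    list(
      y = as.numeric(y), x = as.numeric(x),
      f_star_1 = if (has_fiber) as.numeric(f_star_1),
      f_star_2 = if (has_fiber) as.numeric(f_star_2),
      f_bar = if (has_fiber) (as.numeric(f_star_1) + as.numeric(f_star_2)) / 2,
      c = c, n = n
    ),
    class = "design_bundle"
  )
}

#' @export
print.design_bundle <- function(x, ...) {
  cat(sprintf("Design bundle: n = %d, %s, %d covariate column(s)\n",
              x$n,
              if (is.null(x$f_star_1)) "no fiber replicates"
              else "two fiber replicates", ncol(x$c)))
  invisible(x)
}

# analysis configuration --------------------------------------------------

#' Analysis configuration
#'
#' Collects every tunable of the pipeline: the analyte and fiber variable,
#' the shift applied before the log transform, the outlier cut, the sampler
#' settings, the prior specification, and the random seed.
#'
#' @param pfas_analyte One of `"PFOA"`, `"PFOS"`, `"PFNA"`.
#' @param fiber_type One of `"none"`, `"total"`, `"soluble"`.
#' @param shift_gd Shift in g/d added to energy-adjusted fiber residuals
#'   before the log transform, so the argument of `ln` is positive. Default
#'   40 g/d.
#' @param outlier_z Standard-deviation multiple beyond which ln-transformed
#'   fiber or cholesterol marks a subject as an outlier; default 2.57 (the
#'   99th-percentile band of the normal distribution).
#' @param mcmc List of sampler settings: `chains` (>= 2), `iterations`
#'   per chain, `warmup_fraction` discarded, and the Hamiltonian-specific
#'   settings `max_tree_depth` and `target_accept` which are recorded in run
#'   logs for completeness but inert under the package's Gibbs sampler.
#' @param priors A [prior_spec()] or `NULL` for data-scaled defaults.
#' @param include_bmi Include body mass index in the covariate block.
#' @param seed Integer random seed.
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(pfas_analyte = c("PFOA", "PFOS", "PFNA"),
                            fiber_type = c("soluble", "total", "none"),
                            shift_gd = 40,
                            outlier_z = 2.57,
                            mcmc = list(),
                            priors = NULL,
                            include_bmi = FALSE,
                            seed = 1L) {
  pfas_analyte <- match.arg(pfas_analyte)
  fiber_type <- match.arg(fiber_type)
  if (!is.numeric(shift_gd) || shift_gd <= 0) {
    stop("`shift_gd` must be > 0", call. = FALSE)
  }
  if (!is.numeric(outlier_z) || outlier_z <= 0) {
    stop("`outlier_z` must be > 0", call. = FALSE)
  }
  mcmc_defaults <- list(chains = 4L, iterations = 2500L,
                        warmup_fraction = 0.5, max_tree_depth = 15L,
                        target_accept = 0.8)
  mcmc <- utils::modifyList(mcmc_defaults, mcmc)
  if (mcmc$chains < 2L) stop("`mcmc$chains` must be >= 2", call. = FALSE)
  if (mcmc$warmup_fraction <= 0 || mcmc$warmup_fraction >= 1) {
    stop("`mcmc$warmup_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(pfas_analyte = pfas_analyte, fiber_type = fiber_type,
         shift_gd = shift_gd, outlier_z = outlier_z, mcmc = mcmc,
         priors = priors, include_bmi = include_bmi,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}
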