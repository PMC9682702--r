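# pipeline orchestration and display-scaled table rendering

# display scales: PFAS coefficients printed x 1e3, fiber x 1e2
.pfas_scale <- 1e3
.fiber_scale <- 1e2

#' Render the coefficient table
#'
#' Formats OLS (and optionally Bayesian) results in the standard layout:
#' one row per fiber variable (`None`, `Total fiber`, `Soluble fiber`),
#' columns for the fiber and PFAS coefficients of each method, cells as
#' `"coef (error)"` with two decimals. PFAS coefficients and their errors
#' are scaled by 1e3 and fiber by 1e2 at render time only; computation
#' everywhere uses raw scales. Missing cells (the fiber column of the
#' fiber-free model, or an absent Bayesian fit) render as `"N/A"`.
#'
#' @param fits Named list of `ols_fit` objects keyed
#'   `"<ANALYTE>.<fiber>"` (as produced by [run_table1()]`$fits`).
#' @param bayes Optional named list of `bayes_fit` objects with the same
#'   keys.
#' @param analyte Which analyte's column to render, default `"PFOA"`.
#' @return A data.frame of formatted strings with class `table1_render`;
#'   attribute `raw` keeps the unscaled numbers.
#' @export
render_table1 <- function(fits, bayes = NULL, analyte = "PFOA") {
  fmt <- function(est, err) {
    if (is.null(est) || is.na(est)) return("N/A")
    sprintf("%.2f (%.2f)", est, err)
  }
  rows <- c(none = "None", total = "Total fiber", soluble = "Soluble fiber")
  out <- data.frame(fiber_variable = unname(rows),
                    fiber_ols = "N/A", fiber_bayes = "N/A",
                    pfas_ols = "N/A", pfas_bayes = "N/A",
                    stringsAsFactors = FALSE)
  raw <- list()
  for (i in seq_along(rows)) {
    ft <- names(rows)[i]
    key <- paste(analyte, ft, sep = ".")
    f <- fits[[key]]
    if (!is.null(f)) {
      out$pfas_ols[i] <- fmt(f$coefficients[["x"]] * .pfas_scale,
                             f$standard_errors[["x"]] * .pfas_scale)
      raw[[paste0(ft, ".pfas_ols")]] <- f$coefficients[["x"]]
      if (ft != "none" && "f_bar" %in% names(f$coefficients)) {
        out$fiber_ols[i] <- fmt(f$coefficients[["f_bar"]] * .fiber_scale,
                                f$standard_errors[["f_bar"]] * .fiber_scale)
        raw[[paste0(ft, ".fiber_ols")]] <- f$coefficients[["f_bar"]]
      }
    }
    b <- bayes[[key]]
    if (!is.null(b)) {
      tab <- b$summary$table
      g <- function(p) tab[tab$parameter == p, , drop = FALSE]
      bx <- g("beta_x")
      if (nrow(bx)) {
        out$pfas_bayes[i] <- fmt(bx$mean * .pfas_scale, bx$sd * .pfas_scale)
        raw[[paste0(ft, ".pfas_bayes")]] <- bx$mean
      }
      bf <- g("beta_f")
      if (ft != "none" && nrow(bf)) {
        out$fiber_bayes[i] <- fmt(bf$mean * .fiber_scale,
                                  bf$sd * .fiber_scale)
        raw[[paste0(ft, ".fiber_bayes")]] <- bf$mean
      }
    }
  }
  structure(out, raw = raw, analyte = analyte, class = c("table1_render",
                                                         "data.frame"))
}

#' Invert the display scaling of a rendered cell
#'
#' @param cell A rendered string like `"2.59 (0.75)"`.
#' @param scale The display scale applied (1e3 for PFAS, 1e2 for fiber).
#' @return The point estimate on the raw scale, or `NA` for `"N/A"`.
#' @export
unscale_cell <- function(cell, scale) {
  if (identical(cell, "N/A")) return(NA_real_)
  as.numeric(sub(" .*$", "", cell)) / scale
}

#' Run the full analysis pipeline
#'
#' Executes read (when `input` is a path) -> exclusion cascade -> the
#' nine-model OLS grid -> optional Bayesian fits -> change-in-estimate
#' assessments, and returns everything as one report bundle. With
#' `out_dir` set, also writes the rendered table (CSV), the raw results
#' and run log (JSON), and the exclusion report (JSON).
#'
#' Bayesian fitting on large samples is opt-in via `bayes_analytes`
#' because sampling a latent value per subject is the expensive stage;
#' each requested analyte gets a fiber-free fit plus one fit per fiber
#' type.
#'
#' @param input A CSV path or a [subject_records()] data.frame.
#' @param config An [analysis_config()].
#' @param bayes_analytes Character vector of analytes to fit Bayesian
#'   models for (subset of `c("PFOA", "PFOS", "PFNA")`); empty (default)
#'   skips MCMC.
#' @param bayes_fiber_types Fiber types for the Bayesian fits, default
#'   `c("total", "soluble")`.
#' @param dictionary Optional column dictionary for [read_analytic_csv()].
#' @param out_dir Optional output directory.
#' @return An object of class `pipeline_report`: `table1` (rendered),
#'   `ols` (the `table1_fits`), `bayes` (list or `NULL`),
#'   `assessments_bayes`, `exclusions`, `n`, `log`.
#' @export
run_pipeline <- function(input, config = analysis_config(),
                         bayes_analytes = character(0),
                         bayes_fiber_types = c("total", "soluble"),
                         dictionary = NULL, out_dir = NULL) {
  records <- if (is.character(input)) {
    read_analytic_csv(input, dictionary)
  } else if (inherits(input, "subject_records")) {
    input
  } else {
    stop("stage 'read' failed: input must be a CSV path or subject_records",
         call. = FALSE)
  }
  records <- sum_isomers(records)

  ols <- tryCatch(run_table1(records, config), error = function(e) {
    stop("stage 'ols' failed: ", conditionMessage(e), call. = FALSE)
  })

  bayes <- NULL
  assessments_bayes <- NULL
  if (length(bayes_analytes)) {
    bayes_analytes <- match.arg(bayes_analytes, c("PFOA", "PFOS", "PFNA"),
                                several.ok = TRUE)
    retained <- apply_exclusions(records, config)$records
    bayes <- list()
    assessments_bayes <- list()
    for (analyte in bayes_analytes) {
      cfg <- config
      cfg$pfas_analyte <- analyte
      cfg$fiber_type <- "none"
      bundle0 <- build_design_bundle(retained, cfg)
      fit0 <- fit_bayes(bundle0, priors = config$priors,
                        settings = config$mcmc, seed = config$seed)
      bayes[[paste(analyte, "none", sep = ".")]] <- fit0
      for (ft in bayes_fiber_types) {
        cfg$fiber_type <- ft
        bundle <- build_design_bundle(retained, cfg)
        fit <- fit_bayes(bundle, priors = config$priors,
                         settings = config$mcmc, seed = config$seed)
        bayes[[paste(analyte, ft, sep = ".")]] <- fit
        assessments_bayes[[paste(analyte, ft, sep = ".")]] <-
          compare_models(fit0, fit)
      }
    }
  }

  table1 <- render_table1(ols$fits, bayes)
  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    config = list(shift_gd = config$shift_gd, outlier_z = config$outlier_z,
                  mcmc = config$mcmc, include_bmi = config$include_bmi),
    n_retained = ols$n,
    bayes_analytes = bayes_analytes,
    versions = list(
      r = paste(R.version$major, R.version$minor, sep = "."),
      pfasfiber = as.character(utils::packageVersion("pfasfiber"))
    )
  )
  report <- structure(
    list(table1 = table1, ols = ols, bayes = bayes,
         assessments_bayes = assessments_bayes,
         exclusions = ols$exclusions, n = ols$n, log = log),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (n = %d)\n\n", x$n))
  print(as.data.frame(x$table1), row.names = FALSE)
  cat("\nChange-in-estimate (OLS):\n")
  for (nm in names(x$ols$assessments)) {
    cat(sprintf("  %-14s %+.1f%%\n", nm,
                x$ols$assessments[[nm]]$percent_change))
  }
  if (!is.null(x$assessments_bayes)) {
    cat("Change-in-estimate (Bayesian):\n")
    for (nm in names(x$assessments_bayes)) {
      cat(sprintf("  %-14s %+.1f%%\n", nm,
                  x$assessments_bayes[[nm]]$percent_change))
    }
  }
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' @param report A `pipeline_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$table1),
                   file.path(out_dir, "table1.csv"), row.names = FALSE)
  raw <- list(
    n = report$n,
    ols = lapply(report$ols$fits, function(f) {
      list(coefficients = as.list(f$coefficients),
           standard_errors = as.list(f$standard_errors),
           n = f$n, aic = f$aic)
    }),
    ols_percent_change = lapply(report$ols$assessments, function(a) {
      list(percent_change = a$percent_change, flagged = a$flagged)
    }),
    bayes_percent_change = if (!is.null(report$assessments_bayes)) {
      lapply(report$assessments_bayes, function(a) {
        list(percent_change = a$percent_change, flagged = a$flagged)
      })
    },
    log = report$log
  )
  writeLines(jsonlite::toJSON(raw, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(out_dir, "results.json"))
  exclusion_report_json(report$exclusions,
                        file.path(out_dir, "exclusions.json"))
  invisible(out_dir)
}
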