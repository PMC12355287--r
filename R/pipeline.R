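md5_of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

outcome_formula <- function(outcome, covariates) {
  rhs <- paste(covariates, collapse = " + ")
  txt <- switch(outcome,
    dgf = paste("dgf ~", rhs),
    rejection = paste("rejection ~", rhs),
    death = paste("survival::Surv(months_death, event_death) ~", rhs),
    graft = paste("survival::Surv(months_graft, event_graft) ~", rhs),
    stop("unknown outcome: ", outcome))
  as.formula(txt, env = asNamespace("wqsmix"))
}

#' Run the full mixture-analysis pipeline
#'
#' Orchestrates every stage end to end: obtain a cohort (simulated
#' from \code{config}, or supplied), link the annual constituent panel
#' via the pre-transplant moving average, decile-transform, split,
#' estimate bootstrap weights, fit the stage-2 model for each requested
#' outcome, optionally fit interaction models for effect-measure
#' modification and a truncated-follow-up sensitivity analysis, and
#' assemble a provenance manifest.  Any stage failure aborts with the
#' stage name.
#'
#' @param config a \code{\link{sim_config}}; supplies the synthetic
#'   cohort and the analysis settings (q, B, train_fraction, seed).
#' @param data optional list with elements \code{panel} and
#'   \code{cohort} to analyze instead of simulating; the cohort must
#'   contain the outcome and covariate columns.
#' @param outcomes subset of \code{c("dgf", "rejection", "death",
#'   "graft")}; stages for omitted outcomes are skipped cleanly.
#' @param covariates covariate column names for adjustment.
#' @param modifiers optional binary modifier columns; each gets an
#'   interaction fit per outcome.
#' @param horizon optional follow-up truncation (months) applied to the
#'   survival outcomes as a sensitivity analysis alongside the primary
#'   fits.
#' @param out_dir optional directory: writes per-outcome weight CSVs,
#'   fit JSONs and the manifest JSON.
#' @param include_timestamp add a wall-clock timestamp to the manifest
#'   (off by default so identical config and seed reproduce a
#'   byte-identical bundle).
#' @return list of class \code{wqs_pipeline}: \code{fits} (one
#'   \code{\link{wqs}} object per outcome), \code{interactions},
#'   \code{sensitivity}, \code{manifest}.
#' @export
run_wqs_pipeline <- function(config = sim_config(), data = NULL,
                             outcomes = c("dgf", "rejection",
                                          "death", "graft"),
                             covariates = c("age", "sex",
                                            "donor_deceased", "cit",
                                            "deprivation"),
                             modifiers = character(0),
                             horizon = NULL, out_dir = NULL,
                             include_timestamp = FALSE) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(data)) {
    sim <- stage("simulate", simulate_wqs_cohort(config))
    tab <- stage("link", wqs_analysis_table(sim))
    input_digest <- md5_of(list(config = unclass(config)))
  } else {
    tab <- stage("link", {
      expo <- link_exposures(data$panel, data$cohort, policy = "drop")
      merge(data$cohort, expo, by = "id", sort = TRUE)
    })
    sim <- NULL
    input_digest <- md5_of(data)
  }
  missing_cov <- setdiff(covariates, names(tab))
  if (length(missing_cov))
    stop("pipeline stage 'covariates' failed: missing columns: ",
         paste(missing_cov, collapse = ", "))

  fits <- list()
  interactions <- list()
  sensitivity <- list()
  for (oc in outcomes) {
    f <- outcome_formula(oc, covariates)
    fits[[oc]] <- stage(paste0("fit-", oc),
      wqs(f, data = tab, mixture = config$constituents,
          q = config$q, B = config$B,
          train_fraction = config$train_fraction,
          max_months = config$max_months, seed = config$seed))
    if (length(modifiers))
      interactions[[oc]] <- stage(paste0("interaction-", oc),
        lapply(setNames(modifiers, modifiers), function(mdf) {
          # age and CIT enter Table-3-style subgroup fits as the usual
          # clinical dichotomies; other modifiers must already be binary
          vals <- switch(mdf,
                         age = as.integer(tab$age >= 55),
                         cit = as.integer(tab$cit > 12),
                         NULL)
          wqs_interaction(fits[[oc]], mdf, values = vals)
        }))
    if (!is.null(horizon) && oc %in% c("death", "graft"))
      sensitivity[[oc]] <- stage(paste0("sensitivity-", oc),
        wqs(f, data = tab, mixture = config$constituents,
            q = config$q, B = config$B,
            train_fraction = config$train_fraction,
            max_months = config$max_months, horizon = horizon,
            seed = config$seed))
  }

  manifest <- list(
    package = "wqsmix",
    version = as.character(utils::packageVersion("wqsmix")),
    seed = config$seed,
    config_digest = md5_of(unclass(config)),
    input_digest = input_digest,
    outcomes = outcomes,
    covariates = covariates,
    q = config$q, B = config$B,
    train_fraction = config$train_fraction,
    timestamp = if (include_timestamp)
      format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NULL)

  out <- list(fits = fits, interactions = interactions,
              sensitivity = sensitivity, manifest = manifest,
              sim = sim)
  class(out) <- "wqs_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.wqs_pipeline <- function(x, ...) {
  cat("WQS mixture-analysis pipeline (seed ", x$manifest$seed, ")\n",
      sep = "")
  for (oc in names(x$fits)) {
    f <- x$fits[[oc]]
    lab <- if (f$family == "binomial") "aOR" else "aHR"
    cat(sprintf("  %-10s %s %.4f (95%% CI %.4f-%.4f); top: %s\n",
                oc, lab, f$effect, f$effect_ci95[1], f$effect_ci95[2],
                names(which.max(f$weights))))
  }
  invisible(x)
}

#' Write relative-importance report files for a set of fits
#'
#' Emits one CSV per outcome with each constituent's mean weight,
#' relative importance in percent (summing to 100 within rounding,
#' descending), and the bootstrap count; optionally a bar chart per
#' outcome.  Every number is taken from the fit object — nothing is
#' recomputed at render time.
#'
#' @param fits named list of \code{\link{wqs}} fits.
#' @param dir output directory (created if needed).
#' @param plot also write a PNG bar chart per outcome.
#' @return invisibly, the paths written.
#' @export
render_weight_report <- function(fits, dir, plot = FALSE) {
  if (!length(fits)) stop("need at least one fit to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (oc in names(fits)) {
    wt <- weight_table(fits[[oc]])
    wt$n_boot_used <- fits[[oc]]$n_boot_used
    p <- file.path(dir, paste0("weights_", oc, ".csv"))
    utils::write.csv(wt, p, row.names = FALSE)
    paths <- c(paths, p)
    if (plot) {
      pp <- file.path(dir, paste0("weights_", oc, ".png"))
      ok <- tryCatch({
        grDevices::png(pp, width = 900, height = 600)
        plot(fits[[oc]])
        grDevices::dev.off()
        TRUE
      }, error = function(e) FALSE)
      if (ok) paths <- c(paths, pp)
    }
  }
  invisible(paths)
}

write_pipeline_outputs <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  render_weight_report(pipeline$fits, dir)
  for (oc in names(pipeline$fits)) {
    f <- pipeline$fits[[oc]]
    jsonlite::write_json(
      list(outcome = oc, family = f$family, beta1 = f$beta1,
           se = f$se, ci95 = f$ci95, effect = f$effect,
           effect_ci95 = f$effect_ci95,
           percent_increase = f$percent_increase,
           percent_increase_ci95 = f$percent_increase_ci95,
           n = f$n, n_events = f$n_events,
           n_boot_used = f$n_boot_used,
           coefficients = as.list(f$coefficients)),
      file.path(dir, paste0("fit_", oc, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(pipeline$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
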