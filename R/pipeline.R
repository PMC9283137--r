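# Orchestration: in-memory two-step analysis, YAML-driven end-to-end runs,
# reverse MR, logging.

#' @export
`[.summary_stats` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "trait_label") <- attr(x, "trait_label")
    attr(out, "trait_type") <- attr(x, "trait_type")
    attr(out, "unit") <- attr(x, "unit")
    class(out) <- c("summary_stats", "data.frame")
  }
  out
}

restrict_snps <- function(ss, ids) ss[ss$snp %in% ids, , drop = FALSE]

#' Two-step MVMR mediation analysis, in memory
#'
#' Runs the complete analysis graph on harmonisable summary statistics:
#' (1) total effect of the exposure on the outcome by IVW over the
#' exposure's instruments, with MR-Egger, weighted-median and Cochran's Q
#' sensitivity analyses; (2) exposure->mediator effects by univariable IVW
#' (step 1); (3) exposure-adjusted mediator->outcome effects, the exposure's
#' direct effect, conditional F statistics, and MVMR-Egger over the union of
#' instruments (step 2); (4) individual mediation by both the
#' product-of-coefficients and difference methods with delta-method
#' proportion-mediated intervals; (5) combined mediation by the difference
#' method over all mediator combinations up to `max_combo`.
#'
#' @param exposure [summary_stats()] for the exposure (all SNPs, not only
#'   instruments).
#' @param mediators named list of mediator [summary_stats()].
#' @param outcome outcome [summary_stats()].
#' @param instruments named list of instrument SNP-id vectors: one entry per
#'   trait label (exposure and each mediator), e.g. from
#'   [select_instruments()] or a simulation's truth.
#' @param ivw_model passed to [mr_ivw()].
#' @param eaf_ambiguity passed to [harmonise()].
#' @param max_combo largest mediator-combination size (default 6).
#' @param combinations run the combined-mediation lattice (default TRUE).
#' @param sensitivity run Egger/weighted-median/MVMR-Egger analyses.
#' @param n_boot,seed weighted-median bootstrap control (seed mandatory).
#' @return list of class `two_step_result` with tables `total`, `step1`,
#'   `step2`, `individual`, `combined`, `sensitivity`, and the underlying
#'   estimate objects in `$objects`.
#' @export
two_step_mediation <- function(exposure, mediators, outcome, instruments,
                               ivw_model = "multiplicative-random",
                               eaf_ambiguity = c(0.3, 0.7),
                               max_combo = 6L, combinations = TRUE,
                               sensitivity = TRUE, n_boot = 1000L, seed) {
  if (missing(seed)) config_error("two_step_mediation requires a seed")
  exp_label <- trait_label(exposure)
  med_labels <- names(mediators)
  needed <- c(exp_label, med_labels)
  miss <- setdiff(needed, names(instruments))
  if (length(miss))
    config_error(paste0("missing instrument list(s) for: ",
                        paste(miss, collapse = ", ")))

  # total effect over the exposure's instruments
  h_total <- harmonise(restrict_snps(exposure, instruments[[exp_label]]),
                       outcome, eaf_ambiguity)
  total <- mr_ivw(h_total, model = ivw_model)
  sens <- list()
  if (sensitivity) {
    sens$total_egger <- mr_egger(h_total)
    sens$total_wmedian <- mr_weighted_median(h_total, n_boot = n_boot,
                                             seed = seed)
  }

  # step 1: exposure -> mediator, univariable IVW over exposure instruments
  alphas <- lapply(med_labels, function(mlab) {
    h <- harmonise(restrict_snps(exposure, instruments[[exp_label]]),
                   mediators[[mlab]], eaf_ambiguity)
    mr_ivw(h, model = ivw_model)
  })
  names(alphas) <- med_labels

  # step 2: mediator -> outcome adjusted for the exposure, over the union of
  # both traits' instruments
  build_h <- function(set) {
    ids <- unique(unlist(c(instruments[exp_label], instruments[set])))
    harmonise(c(list(restrict_snps(exposure, ids)),
                lapply(mediators[set], restrict_snps, ids = ids)),
              outcome, eaf_ambiguity)
  }
  step2 <- lapply(med_labels, function(mlab) {
    h <- build_h(mlab)
    res <- mvmr_ivw(h)
    egger <- if (sensitivity) mvmr_egger(h) else NULL
    list(mvmr = res, egger = egger,
         theta = mr_estimate("mvmr-direct", res$beta[[mlab]], res$se[[mlab]],
                             res$n_snp, exposure = mlab, outcome = res$outcome,
                             outcome_type = res$outcome_type),
         direct = mr_estimate("mvmr-direct", res$beta[[exp_label]],
                              res$se[[exp_label]], res$n_snp,
                              exposure = exp_label, outcome = res$outcome,
                              outcome_type = res$outcome_type))
  })
  names(step2) <- med_labels

  # individual mediation, product and difference
  individual <- list()
  for (mlab in med_labels) {
    ind_p <- indirect_product(alphas[[mlab]], step2[[mlab]]$theta)
    individual[[paste0(mlab, ".product")]] <-
      mediation_result(mlab, "product", total, ind_p)
    ind_d <- indirect_difference(total, step2[[mlab]]$direct)
    individual[[paste0(mlab, ".difference")]] <-
      mediation_result(mlab, "difference", total, ind_d,
                       direct = step2[[mlab]]$direct)
  }

  combined <- NULL
  if (combinations && length(med_labels) >= 1L) {
    combined <- combined_mediation(
      function(set) build_h(set), total,
      mediator_combinations(med_labels, max_combo))
  }

  binary <- identical(trait_type(outcome), "binary-logodds")
  structure(list(
    total = mr_report(c(list(total), sens)),
    step1 = mr_report(alphas),
    step2 = do.call(rbind, lapply(med_labels, function(mlab)
      as.data.frame(step2[[mlab]]$mvmr))),
    individual = mediation_report(individual, binary_outcome = binary),
    combined = if (!is.null(combined))
      mediation_report(combined, binary_outcome = binary),
    sensitivity = if (sensitivity)
      do.call(rbind, lapply(med_labels, function(mlab)
        cbind(mediator = mlab, as.data.frame(step2[[mlab]]$egger)))),
    objects = list(total = total, alphas = alphas, step2 = step2,
                   individual = individual, combined = combined,
                   h_total = h_total, sens = sens, build_h = build_h)),
    class = "two_step_result")
}

#' Reverse MR: mediators as exposures of the primary exposure
#'
#' For each mediator, runs the univariable estimator suite (IVW, MR-Egger
#' with its intercept test, weighted median) using the mediator's own
#' instruments with the primary exposure as outcome, to detect
#' bidirectionality. The output schema matches the forward estimator table.
#'
#' @param mediators named list of mediator [summary_stats()].
#' @param exposure the primary exposure's [summary_stats()], used as the
#'   outcome here.
#' @param instruments named list of instrument id vectors per mediator.
#' @param eaf_ambiguity,ivw_model,n_boot,seed as in [two_step_mediation()].
#' @return data frame, one row per (mediator, method).
#' @export
reverse_mr <- function(mediators, exposure, instruments,
                       eaf_ambiguity = c(0.3, 0.7),
                       ivw_model = "multiplicative-random",
                       n_boot = 1000L, seed) {
  if (missing(seed)) config_error("reverse_mr requires a seed")
  rows <- lapply(names(mediators), function(mlab) {
    h <- harmonise(restrict_snps(mediators[[mlab]], instruments[[mlab]]),
                   exposure, eaf_ambiguity)
    ests <- list(mr_ivw(h, model = ivw_model), mr_egger(h),
                 mr_weighted_median(h, n_boot = n_boot, seed = seed))
    mr_report(ests)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()] from a YAML
#' file or an equivalent nested list. Required structure:
#'
#' ```yaml
#' exposure: EA
#' outcome: T2D
#' mediators: [BMI, TV]
#' seed: 42
#' out_dir: results/
#' traits:
#'   EA:  {file: ea.tsv, trait_type: continuous, unit: "SD (4.2 years)",
#'         p_threshold: 5.0e-8, r2_threshold: 0.1, window: 1.0e6}
#'   ...
#' ld_file: ld.tsv        # optional
#' estimator: {ivw_model: multiplicative-random, n_boot: 1000}
#' max_combo: 6
#' reverse_mr: true
#' eaf_ambiguity: [0.3, 0.7]
#' ```
#'
#' Per-trait instrument thresholds are configuration, not code constants, so
#' source-specific rules (stricter p for one trait, different clumping
#' windows for others) are expressed here. The seed is mandatory because the
#' weighted-median bootstrap is stochastic.
#'
#' @param x YAML file path or a list.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  if (!is.list(cfg)) config_error("config must be a YAML file or a list")
  for (field in c("exposure", "outcome", "traits", "seed", "out_dir"))
    if (is.null(cfg[[field]]))
      config_error(sprintf("config field `%s` is required", field))
  cfg$mediators <- as.character(cfg$mediators %||% character())
  needed <- c(cfg$exposure, cfg$mediators, cfg$outcome)
  miss <- setdiff(needed, names(cfg$traits))
  if (length(miss))
    config_error(paste0("traits missing from config: ",
                        paste(miss, collapse = ", ")))
  for (tr in needed) {
    f <- cfg$traits[[tr]]$file
    if (is.null(f) || !file.exists(f))
      config_error(sprintf("summary-stat file for trait %s not found: %s",
                           tr, f %||% "<missing>"))
  }
  if (!is.null(cfg$ld_file) && !file.exists(cfg$ld_file))
    config_error(sprintf("ld_file not found: %s", cfg$ld_file))
  cfg$estimator <- cfg$estimator %||% list()
  cfg$estimator$ivw_model <- cfg$estimator$ivw_model %||% "multiplicative-random"
  cfg$estimator$n_boot <- as.integer(cfg$estimator$n_boot %||% 1000L)
  cfg$max_combo <- as.integer(cfg$max_combo %||% 6L)
  cfg$reverse_mr <- isTRUE(cfg$reverse_mr %||% TRUE)
  cfg$eaf_ambiguity <- as.numeric(cfg$eaf_ambiguity %||% c(0.3, 0.7))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the end-to-end pipeline from configuration
#'
#' Reads per-trait summary statistics, selects instruments with the per-trait
#' thresholds (p-value filter + greedy LD clumping), harmonises, and runs
#' [two_step_mediation()] plus optional [reverse_mr()], writing tab-delimited
#' tables, a run log (software versions, config echo, seed) and a
#' machine-readable JSON manifest into `cfg$out_dir`. Stage failures are
#' captured in the manifest while earlier outputs are retained.
#'
#' Outputs: `total_effects.tsv`, `ea_mediator_effects.tsv` (step 1),
#' `mvmr_mediator_effects.tsv` (step 2), `individual_mediation.tsv`,
#' `combined_mediation.tsv`, `sensitivity_mvmr_egger.tsv`,
#' `reverse_mr.tsv`, `mediation_results.json`, `run.log`, `manifest.json`.
#'
#' @param cfg a [pipeline_config()] (or something coercible by it).
#' @return invisibly, the [two_step_mediation()] result (or `NULL` on stage
#'   failure) with attribute `"manifest"`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(status = "ok", stages = list(), errors = list(),
                   seed = cfg$seed)
  log_path <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)
  logline("twostepmr %s | R %s", as.character(utils::packageVersion("twostepmr")),
          paste(R.version$major, R.version$minor, sep = "."))
  logline("started %s, seed %d", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
          cfg$seed)
  logline("config: %s", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))

  result <- NULL
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      manifest$status <<- "error"
      manifest$errors[[name]] <<- conditionMessage(out)
      logline("stage %s FAILED: %s", name, conditionMessage(out))
      NULL
    } else {
      manifest$stages[[name]] <<- "ok"
      logline("stage %s ok", name)
      out
    }
  }

  traits <- stage("read", {
    lapply(stats::setNames(nm = c(cfg$exposure, cfg$mediators, cfg$outcome)),
           function(tr) {
             spec <- cfg$traits[[tr]]
             read_summary_stats(spec$file,
                                column_map = unlist(spec$column_map),
                                trait_label = tr,
                                trait_type = spec$trait_type %||% "continuous",
                                unit = spec$unit %||% NA_character_)
           })
  })
  ld <- if (!is.null(cfg$ld_file)) stage("ld", read_ld_info(cfg$ld_file))
  instruments <- if (!is.null(traits)) stage("instruments", {
    lapply(stats::setNames(nm = c(cfg$exposure, cfg$mediators)), function(tr) {
      spec <- cfg$traits[[tr]]
      sel <- select_instruments(traits[[tr]],
                                p_threshold = spec$p_threshold %||% 5e-8,
                                ld = ld,
                                r2_threshold = spec$r2_threshold %||% 0.1,
                                window = spec$window)
      logline("instruments %s: %d SNPs", tr, nrow(sel))
      sel$snp
    })
  })
  if (!is.null(instruments)) {
    result <- stage("analysis", two_step_mediation(
      exposure = traits[[cfg$exposure]],
      mediators = traits[cfg$mediators],
      outcome = traits[[cfg$outcome]],
      instruments = instruments,
      ivw_model = cfg$estimator$ivw_model,
      eaf_ambiguity = cfg$eaf_ambiguity,
      max_combo = cfg$max_combo,
      n_boot = cfg$estimator$n_boot, seed = cfg$seed))
  }
  if (!is.null(result)) {
    stage("write", {
      write_tsv(result$total, file.path(cfg$out_dir, "total_effects.tsv"))
      write_tsv(result$step1, file.path(cfg$out_dir, "ea_mediator_effects.tsv"))
      write_tsv(result$step2, file.path(cfg$out_dir, "mvmr_mediator_effects.tsv"))
      write_tsv(result$individual,
                file.path(cfg$out_dir, "individual_mediation.tsv"))
      if (!is.null(result$combined))
        write_tsv(result$combined,
                  file.path(cfg$out_dir, "combined_mediation.tsv"))
      if (!is.null(result$sensitivity))
        write_tsv(result$sensitivity,
                  file.path(cfg$out_dir, "sensitivity_mvmr_egger.tsv"))
      jsonlite::write_json(
        lapply(result$objects$individual, function(r) as.data.frame(r)),
        file.path(cfg$out_dir, "mediation_results.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    })
  }
  if (cfg$reverse_mr && !is.null(traits) && !is.null(instruments) &&
      length(cfg$mediators)) {
    rev_tab <- stage("reverse", reverse_mr(
      traits[cfg$mediators], traits[[cfg$exposure]],
      instruments[cfg$mediators],
      eaf_ambiguity = cfg$eaf_ambiguity,
      ivw_model = cfg$estimator$ivw_model,
      n_boot = cfg$estimator$n_boot, seed = cfg$seed))
    if (!is.null(rev_tab))
      write_tsv(rev_tab, file.path(cfg$out_dir, "reverse_mr.tsv"))
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("finished %s, status %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
          manifest$status)
  invisible(structure(result %||% list(), manifest = manifest))
}
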