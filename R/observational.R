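# Traditional regression-based mediation on individual-level data, for
# triangulation against the MR estimates; runs on simulate()'s cohorts or on
# any cohort table read from CSV.

#' Read an individual-level cohort table
#'
#' Comma- or tab-delimited with a header; `column_map` renames source headers
#' to analysis names, and rows with missing values in the used columns are
#' removed by listwise deletion with a logged count.
#'
#' @param path file path.
#' @param column_map named character vector, analysis name -> source header.
#' @param use_cols columns to require (default: all mapped names).
#' @return data frame.
#' @export
read_cohort_table <- function(path, column_map = NULL, use_cols = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(tbl))
    if (length(miss))
      config_error(paste0("column_map refers to absent column(s): ",
                          paste(miss, collapse = ", ")))
    for (nm in names(column_map)) names(tbl)[names(tbl) == column_map[[nm]]] <- nm
  }
  use_cols <- use_cols %||% names(column_map) %||% names(tbl)
  complete <- stats::complete.cases(tbl[use_cols])
  if (any(!complete))
    message(sprintf("read_cohort_table: %d row(s) removed by listwise deletion",
                    sum(!complete)))
  tbl[complete, , drop = FALSE]
}

check_separation <- function(fit) {
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    input_error("separation suspected in logistic fit (|coefficient| > 15)")
  invisible(fit)
}

#' Observational total effect of the exposure on a binary outcome
#'
#' Logistic regression of the outcome on the exposure plus covariates; the
#' exposure is rescaled so one reported unit equals `ea_scale` raw units
#' (e.g. `ea_scale = 4.2` turns years of schooling into the 4.2-year SD
#' unit). Returns the log odds ratio with its Wald SE.
#'
#' @param tbl cohort data frame.
#' @param ea,outcome column names (outcome must be 0/1).
#' @param covariates character vector of adjustment columns.
#' @param ea_scale raw exposure units per reported unit (default 1).
#' @return An [mr_estimate()] with method `"obs-logistic"`.
#' @export
obs_total_effect <- function(tbl, ea = "ea", outcome = "outcome",
                             covariates = character(), ea_scale = 1) {
  if (nrow(tbl) < 50L) input_error("observational fit needs >= 50 rows")
  if (!all(tbl[[outcome]] %in% c(0, 1)))
    config_error("outcome must be coded 0/1")
  tbl$.ea_scaled <- tbl[[ea]] / ea_scale
  fit <- stats::glm(stats::reformulate(c(".ea_scaled", covariates),
                                       response = outcome),
                    data = tbl, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  check_separation(fit)
  cs <- summary(fit)$coefficients[".ea_scaled", ]
  mr_estimate("obs-logistic", cs[["Estimate"]], cs[["Std. Error"]],
              n_snp = NA_integer_, exposure = ea, outcome = outcome,
              outcome_type = "binary-logodds")
}

obs_decomposition <- function(tbl, ea, outcome, mediator_set, covariates,
                              method, ea_scale) {
  total <- obs_total_effect(tbl, ea, outcome, covariates, ea_scale)
  tbl$.ea_scaled <- tbl[[ea]] / ea_scale
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 50)
  adj_fit <- stats::glm(
    stats::reformulate(c(".ea_scaled", mediator_set, covariates),
                       response = outcome),
    data = tbl, family = stats::binomial(), control = ctrl)
  check_separation(adj_fit)
  if (method == "difference") {
    direct_beta <- stats::coef(adj_fit)[[".ea_scaled"]]
    ind <- total$beta - direct_beta
  } else {
    ind <- 0
    for (m in mediator_set) {
      binary_med <- all(tbl[[m]] %in% c(0, 1))
      a_fit <- if (binary_med)
        stats::glm(stats::reformulate(c(".ea_scaled", covariates),
                                      response = m),
                   data = tbl, family = stats::binomial(), control = ctrl)
      else
        stats::lm(stats::reformulate(c(".ea_scaled", covariates),
                                     response = m), data = tbl)
      ind <- ind + stats::coef(a_fit)[[".ea_scaled"]] * stats::coef(adj_fit)[[m]]
    }
  }
  list(total = total$beta, indirect = ind, pm = ind / total$beta)
}

#' Observational mediation analysis (product or difference method)
#'
#' Product of coefficients: each mediator is regressed on the exposure plus
#' covariates (linear, or logistic for a 0/1 mediator so its leg is a
#' log-OR), the outcome is regressed on exposure + mediators + covariates
#' (logistic), and the indirect effect is the sum of `alpha * theta` products
#' on the log-odds scale. Difference method: total log-OR minus the
#' mediator-adjusted log-OR. Confidence intervals for the proportion
#' mediated come from a seeded nonparametric bootstrap (percentile).
#'
#' @param tbl cohort data frame.
#' @param mediator_set character vector of mediator columns.
#' @param method `"product"` or `"difference"`.
#' @param ea,outcome,covariates,ea_scale as in [obs_total_effect()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory).
#' @return A [mediation_result()] with bootstrap-percentile `pm` CI.
#' @export
obs_mediation <- function(tbl, mediator_set,
                          method = c("product", "difference"),
                          ea = "ea", outcome = "outcome",
                          covariates = character(), ea_scale = 1,
                          n_boot = 1000L, seed) {
  method <- match.arg(method)
  if (missing(seed)) config_error("obs_mediation requires a seed")
  if (!all(mediator_set %in% names(tbl)))
    config_error("mediator columns missing from table")
  point <- obs_decomposition(tbl, ea, outcome, mediator_set, covariates,
                             method, ea_scale)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(tbl), replace = TRUE)
      tryCatch(obs_decomposition(tbl[idx, , drop = FALSE], ea, outcome,
                                 mediator_set, covariates, method,
                                 ea_scale)$pm,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  total_est <- obs_total_effect(tbl, ea, outcome, covariates, ea_scale)
  res <- mediation_result(mediator_set, method, total_est,
                          list(beta = point$indirect,
                               se = stats::sd(boots) * abs(point$total)))
  # replace the delta-method interval by the bootstrap percentile interval
  res$pm_se <- stats::sd(boots)
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  res$pm_ci_low <- qs[1]; res$pm_ci_high <- qs[2]
  res
}
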