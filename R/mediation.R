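# Two-step mediation decomposition: product-of-coefficients and
# difference-in-coefficients indirect effects, proportion mediated with
# delta-method intervals, mediator-combination lattice.

coef_se <- function(x, what) {
  if (inherits(x, "mr_estimate")) return(c(x$beta, x$se))
  if (is.list(x) && all(c("beta", "se") %in% names(x)))
    return(c(x$beta, x$se))
  if (is.numeric(x) && length(x) == 2L) return(unname(x))
  config_error(sprintf("`%s` must be an mr_estimate or a (beta, se) pair", what))
}

#' Product-of-coefficients indirect effect
#'
#' Indirect effect of the exposure on the outcome through one mediator:
#' `alpha * theta`, where `alpha` is the exposure-mediator effect (univariable
#' MR) and `theta` the exposure-adjusted mediator-outcome effect (MVMR). Both
#' legs must be on additive scales (log-odds for binary traits). The SE is
#' the first-order product delta method assuming the two legs are
#' independent: `sqrt(alpha^2 se_theta^2 + theta^2 se_alpha^2)`.
#'
#' @param alpha exposure-mediator estimate ([mr_estimate()] or
#'   `list(beta=, se=)`).
#' @param theta exposure-adjusted mediator-outcome estimate.
#' @return `list(beta, se)`.
#' @export
indirect_product <- function(alpha, theta) {
  a <- coef_se(alpha, "alpha"); t <- coef_se(theta, "theta")
  list(beta = a[1] * t[1],
       se = sqrt(a[1]^2 * t[2]^2 + t[1]^2 * a[2]^2))
}

#' Difference-in-coefficients indirect effect
#'
#' `total - direct`, with `direct` the exposure's conditional effect from
#' MVMR adjusted for the mediator set. The SE assumes independence of the two
#' estimates (`sqrt(se_total^2 + se_direct^2)`), a documented approximation.
#'
#' @param total total-effect estimate.
#' @param direct mediator-adjusted direct-effect estimate, on the same scale.
#' @return `list(beta, se)`.
#' @export
indirect_difference <- function(total, direct) {
  tt <- coef_se(total, "total"); d <- coef_se(direct, "direct")
  list(beta = tt[1] - d[1], se = sqrt(tt[2]^2 + d[2]^2))
}

#' Proportion mediated with a delta-method interval
#'
#' `pm = indirect / total` with a first-order ratio delta-method SE treating
#' the two estimates as independent:
#' `se_pm = |pm| sqrt(se_ind^2/ind^2 + se_tot^2/tot^2)`. The proportion and
#' its 95% CI are reported untruncated (values outside `[0, 1]` are possible
#' and informative).
#'
#' @param indirect indirect-effect estimate (`list(beta, se)` or
#'   [mr_estimate()]).
#' @param total total-effect estimate; `total$beta` must be non-zero.
#' @return `list(pm, se, ci_low, ci_high)` (fractions, not percentages).
#' @export
proportion_mediated <- function(indirect, total) {
  ind <- coef_se(indirect, "indirect"); tt <- coef_se(total, "total")
  if (tt[1] == 0) input_error("proportion mediated undefined for total = 0")
  pm <- ind[1] / tt[1]
  se <- if (ind[1] == 0) ind[2] / abs(tt[1])
        else abs(pm) * sqrt(ind[2]^2 / ind[1]^2 + tt[2]^2 / tt[1]^2)
  list(pm = pm, se = se,
       ci_low = pm - z95() * se, ci_high = pm + z95() * se)
}

#' Assemble a mediation result
#'
#' Bundles the decomposition for one named mediator set: total and direct
#' effects, the indirect effect, and the proportion mediated. The exact
#' identities `indirect = alpha * theta` (product) or
#' `indirect = total - direct` (difference) and `pm = indirect / total` hold
#' by construction.
#'
#' @param mediator_set character vector of mediator labels.
#' @param method `"product"` or `"difference"`.
#' @param total total-effect [mr_estimate()].
#' @param direct direct-effect [mr_estimate()] (difference method; optional
#'   for product).
#' @param indirect `list(beta, se)` from [indirect_product()] or
#'   [indirect_difference()].
#' @return An object of class `mediation_result`.
#' @export
mediation_result <- function(mediator_set, method = c("product", "difference"),
                             total, indirect, direct = NULL) {
  method <- match.arg(method)
  pm <- proportion_mediated(indirect, total)
  structure(list(mediator_set = mediator_set, method = method,
                 total = total, direct = direct,
                 indirect_beta = indirect$beta, indirect_se = indirect$se,
                 pm = pm$pm, pm_se = pm$se,
                 pm_ci_low = pm$ci_low, pm_ci_high = pm$ci_high),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> {%s} [%s]\n",
              paste(x$mediator_set, collapse = " + "), x$method))
  cat(sprintf("  total = %.4f (SE %.4f); indirect = %.4f (SE %.4f)\n",
              x$total$beta, x$total$se, x$indirect_beta, x$indirect_se))
  cat(sprintf("  proportion mediated = %.2f%% (95%% CI %.2f%%, %.2f%%)\n",
              100 * x$pm, 100 * x$pm_ci_low, 100 * x$pm_ci_high))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(mediator_set = paste(x$mediator_set, collapse = "+"),
             method = x$method,
             total_beta = x$total$beta, total_se = x$total$se,
             direct_beta = if (is.null(x$direct)) NA_real_ else x$direct$beta,
             direct_se = if (is.null(x$direct)) NA_real_ else x$direct$se,
             indirect_beta = x$indirect_beta, indirect_se = x$indirect_se,
             pm = x$pm, pm_se = x$pm_se,
             pm_ci_low = x$pm_ci_low, pm_ci_high = x$pm_ci_high,
             stringsAsFactors = FALSE)
}

#' Combined mediation over mediator combinations (difference method)
#'
#' For each mediator set, obtains the exposure's direct effect from MVMR
#' adjusted for the whole set (via `h_builder`), forms the combined indirect
#' effect as `total - direct`, and the combined proportion mediated. Failures
#' in individual sets are logged and skipped. Results are sorted by
#' descending proportion mediated.
#'
#' @param h_builder function taking a character vector of mediator labels and
#'   returning a [harmonised_set()] with the primary exposure first and the
#'   mediators after it.
#' @param total total-effect [mr_estimate()].
#' @param mediator_sets list of character vectors; defaults can be built with
#'   [mediator_combinations()].
#' @return list of [mediation_result()]s sorted by descending `pm`, with a
#'   data frame of failed sets in attribute `"failures"`.
#' @export
combined_mediation <- function(h_builder, total, mediator_sets) {
  if (!is.function(h_builder)) config_error("`h_builder` must be a function")
  if (!length(mediator_sets) ||
      any(!vapply(mediator_sets, length, 1L)))
    config_error("each mediator set must be non-empty")
  results <- list()
  failures <- data.frame(mediator_set = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (set in mediator_sets) {
    res <- tryCatch({
      h <- h_builder(set)
      direct <- direct_effect(h)
      ind <- indirect_difference(total, direct)
      mediation_result(set, "difference", total, ind, direct)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(mediator_set = paste(set, collapse = "+"),
                                   error = conditionMessage(res),
                                   stringsAsFactors = FALSE))
    } else results[[length(results) + 1L]] <- res
  }
  ord <- order(-vapply(results, function(r) r$pm, numeric(1)))
  structure(results[ord], failures = failures)
}

#' All non-empty mediator subsets up to a size cap
#'
#' @param mediators character vector of mediator labels.
#' @param max_size largest subset size to enumerate (default 6).
#' @return list of character vectors, smaller sets first.
#' @export
mediator_combinations <- function(mediators, max_size = 6L) {
  max_size <- min(max_size, length(mediators))
  out <- list()
  for (k in seq_len(max_size))
    out <- c(out, utils::combn(mediators, k, simplify = FALSE))
  out
}

#' Tidy table of mediation results
#'
#' @param results list of [mediation_result()]s (e.g. from
#'   [combined_mediation()]).
#' @param binary_outcome add OR presentation columns for total/direct.
#' @return data frame, one row per mediator set.
#' @export
mediation_report <- function(results, binary_outcome = FALSE) {
  if (inherits(results, "mediation_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  if (binary_outcome) {
    tab$total_or <- exp(tab$total_beta)
    tab$direct_or <- exp(tab$direct_beta)
  }
  rownames(tab) <- NULL
  tab
}
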