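# Univariable two-sample MR estimators: Wald ratio, IVW, MR-Egger,
# weighted median, Cochran's Q.

#' Construct an MR estimate record
#'
#' Container for a single causal-effect estimate (on the outcome scale per
#' unit of exposure; log odds ratio when the outcome is binary) with its
#' diagnostics. Mostly produced by the estimator functions.
#'
#' @param method estimator tag, one of `wald`, `ivw-fe`, `ivw-mre`,
#'   `egger-slope`, `weighted-median`, `mvmr-direct`, `obs-logistic`.
#' @param beta,se estimate and standard error (`se > 0`).
#' @param n_snp number of instruments used.
#' @param q,q_df,q_pval Cochran's Q heterogeneity statistic (optional).
#' @param egger_intercept,egger_intercept_se,egger_intercept_pval MR-Egger
#'   intercept triplet (Egger only).
#' @param exposure,outcome trait labels.
#' @param outcome_type `"continuous"` or `"binary-logodds"`.
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snp,
                        q = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_pval = NA_real_,
                        exposure = NA_character_, outcome = NA_character_,
                        outcome_type = "continuous") {
  beta <- unname(beta); se <- unname(se)
  if (!is.finite(se) || se <= 0) input_error("mr_estimate requires se > 0")
  if (!is.na(q) && q < -1e-12) input_error("Cochran's Q cannot be negative")
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - z95() * se, ci_high = beta + z95() * se,
                 pval = z_pval(beta, se), n_snp = n_snp,
                 q = max(q, 0), q_df = q_df, q_pval = q_pval,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_pval = egger_intercept_pval,
                 exposure = exposure, outcome = outcome,
                 outcome_type = outcome_type),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate %s> %s -> %s\n", x$method,
              x$exposure, x$outcome))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n_snp = %d\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  if (x$outcome_type == "binary-logodds")
    cat(sprintf("  OR = %.2f [%.2f, %.2f]\n",
                exp(x$beta), exp(x$ci_low), exp(x$ci_high)))
  if (!is.na(x$q))
    cat(sprintf("  Q = %.3f on %d df (p = %.3g)\n", x$q, x$q_df, x$q_pval))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (SE %.4f, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(exposure = x$exposure, outcome = x$outcome, method = x$method,
             beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, n_snp = x$n_snp, q = x$q, q_df = x$q_df,
             q_pval = x$q_pval, egger_intercept = x$egger_intercept,
             egger_intercept_se = x$egger_intercept_se,
             egger_intercept_pval = x$egger_intercept_pval,
             stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' Per-SNP causal estimate `by / bx` with a delta-method standard error.
#' First order (default): `se = |se_y / bx|`, the conventional weight-giving
#' form. Second order adds the exposure-side term:
#' `sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4)`.
#'
#' @param bx,se_x SNP-exposure effect and SE.
#' @param by,se_y SNP-outcome effect and SE.
#' @param se_order `"first"` or `"second"`.
#' @param exposure,outcome,outcome_type metadata, see [mr_estimate()].
#' @return An [mr_estimate()] with method `"wald"`.
#' @export
wald_ratio <- function(bx, se_x, by, se_y, se_order = c("first", "second"),
                       exposure = NA_character_, outcome = NA_character_,
                       outcome_type = "continuous") {
  se_order <- match.arg(se_order)
  assert_scalar_num(bx, "bx"); assert_scalar_num(by, "by")
  if (bx == 0) input_error("Wald ratio undefined for bx = 0")
  beta <- by / bx
  se <- if (se_order == "first") abs(se_y / bx)
        else sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  mr_estimate("wald", beta, se, 1L, exposure = exposure, outcome = outcome,
              outcome_type = outcome_type)
}

# weighted least squares via the QR of sqrt(w)-scaled design; returns
# coefficients, unscaled (fixed) covariance, and the weighted RSS
wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  Xs <- X * sw
  qr_x <- qr(Xs)
  if (qr_x$rank < ncol(X)) collin_error("rank-deficient weighted design matrix")
  coef <- qr.coef(qr_x, y * sw)
  R <- qr.R(qr_x)
  xtx_inv <- chol2inv(R)
  rss <- sum((y * sw - Xs %*% coef)^2)
  list(coef = as.numeric(coef), vcov_fixed = xtx_inv, rss = rss)
}

#' Inverse-variance-weighted MR estimate
#'
#' Pools per-SNP Wald ratios by inverse-variance weighting with first-order
#' weights, equivalently weighted least squares of outcome betas on exposure
#' betas through the origin with weights `1/outcome_se^2`. Cochran's Q is the
#' weighted residual sum of squares; the multiplicative random-effects model
#' (default, appropriate in the presence of heterogeneity) inflates the SE by
#' `sqrt(max(Q/(n-1), 1))`, the fixed-effect model does not.
#'
#' @param h a [harmonised_set()] with one exposure.
#' @param model `"multiplicative-random"` or `"fixed"`.
#' @return An [mr_estimate()] with method `"ivw-mre"` or `"ivw-fe"`.
#' @export
mr_ivw <- function(h, model = c("multiplicative-random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(h, "harmonised_set"))
  if (n_exposures(h) != 1L) config_error("mr_ivw needs exactly one exposure; see mvmr_ivw")
  n <- n_snps(h)
  bx <- h$exposure_beta[, 1]; by <- h$outcome_beta; sy <- h$outcome_se
  if (n == 1L) {
    est <- wald_ratio(bx, h$exposure_se[, 1], by, sy,
                      exposure = h$exposures, outcome = h$outcome,
                      outcome_type = h$outcome_type)
    est$method <- if (model == "fixed") "ivw-fe" else "ivw-mre"
    return(est)
  }
  w <- 1 / sy^2
  fit <- wls_fit(matrix(bx, ncol = 1), by, w)
  beta <- fit$coef
  se_fixed <- sqrt(fit$vcov_fixed[1, 1])
  q <- fit$rss
  q_df <- n - 1L
  scale <- sqrt(max(q / q_df, 1))
  se <- if (model == "fixed") se_fixed else se_fixed * scale
  mr_estimate(if (model == "fixed") "ivw-fe" else "ivw-mre", beta, se, n,
              q = q, q_df = q_df,
              q_pval = stats::pchisq(q, q_df, lower.tail = FALSE),
              exposure = h$exposures, outcome = h$outcome,
              outcome_type = h$outcome_type)
}

# flip SNP rows so the (first) exposure's betas are non-negative; required
# for an interpretable Egger intercept
orient_positive <- function(h, col = 1L) {
  flip <- h$exposure_beta[, col] < 0
  h$exposure_beta[flip, ] <- -h$exposure_beta[flip, , drop = FALSE]
  h$outcome_beta[flip] <- -h$outcome_beta[flip]
  h
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas *with* an
#' intercept (weights `1/outcome_se^2`), after orienting all SNPs to
#' non-negative exposure betas. The slope is a pleiotropy-robust causal
#' estimate under the InSIDE assumption; a non-zero intercept indicates
#' directional horizontal pleiotropy. SEs use multiplicative residual
#' scaling floored at 1.
#'
#' @param h a [harmonised_set()] with one exposure and at least 3 SNPs.
#' @return An [mr_estimate()] with method `"egger-slope"` and the intercept
#'   triplet filled in.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonised_set"))
  if (n_exposures(h) != 1L) config_error("mr_egger needs exactly one exposure")
  n <- n_snps(h)
  if (n < 3L) input_error("MR-Egger needs at least 3 instruments")
  h <- orient_positive(h)
  bx <- h$exposure_beta[, 1]; by <- h$outcome_beta
  w <- 1 / h$outcome_se^2
  fit <- wls_fit(cbind(1, bx), by, w)
  scale <- sqrt(max(fit$rss / (n - 2L), 1))
  ses <- sqrt(diag(fit$vcov_fixed)) * scale
  mr_estimate("egger-slope", fit$coef[2], ses[2], n,
              q = fit$rss, q_df = n - 2L,
              q_pval = stats::pchisq(fit$rss, n - 2L, lower.tail = FALSE),
              egger_intercept = fit$coef[1], egger_intercept_se = ses[1],
              egger_intercept_pval = z_pval(fit$coef[1], ses[1]),
              exposure = h$exposures, outcome = h$outcome,
              outcome_type = h$outcome_type)
}

# interpolated 50th weighted percentile on cumulative weights minus
# half-weight (standard weighted-median rule)
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cums <- cumsum(w) - w / 2
  if (cums[1] >= 0.5) return(b[1])
  if (cums[length(b)] <= 0.5) return(b[length(b)])
  below <- max(which(cums < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cums[below]) / (cums[below + 1] - cums[below])
}

#' Weighted-median MR estimate
#'
#' The inverse-variance-weighted median of per-SNP Wald ratios: consistent
#' when at least half the total instrument weight comes from valid
#' instruments. The SE comes from a seeded parametric bootstrap that redraws
#' each SNP's exposure and outcome betas from normal distributions with the
#' reported SEs.
#'
#' @param h a [harmonised_set()] with one exposure and at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; mandatory for reproducibility.
#' @return An [mr_estimate()] with method `"weighted-median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed) {
  stopifnot(inherits(h, "harmonised_set"))
  if (missing(seed)) config_error("mr_weighted_median requires a seed")
  if (n_exposures(h) != 1L) config_error("mr_weighted_median needs exactly one exposure")
  n <- n_snps(h)
  if (n < 3L) input_error("weighted median needs at least 3 instruments")
  bx <- h$exposure_beta[, 1]; sx <- h$exposure_se[, 1]
  by <- h$outcome_beta; sy <- h$outcome_se
  ratios <- by / bx
  w <- (bx / sy)^2                      # inverse first-order ratio variance
  beta <- weighted_median_point(ratios, w)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxb <- stats::rnorm(n, bx, sx)
      byb <- stats::rnorm(n, by, sy)
      weighted_median_point(byb / bxb, (bxb / sy)^2)
    }, numeric(1))
  })
  mr_estimate("weighted-median", beta, stats::sd(boots), n,
              exposure = h$exposures, outcome = h$outcome,
              outcome_type = h$outcome_type)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (theta_i - theta_ivw)^2` over per-SNP Wald ratios with
#' first-order inverse-variance weights; compared to a chi-square with
#' `n_snp - 1` degrees of freedom. Excess Q suggests horizontal pleiotropy.
#'
#' @param h a [harmonised_set()] with one exposure and at least 2 SNPs.
#' @return list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(h) {
  stopifnot(inherits(h, "harmonised_set"))
  if (n_exposures(h) != 1L) config_error("cochran_q needs exactly one exposure")
  n <- n_snps(h)
  if (n < 2L) input_error("Cochran's Q needs at least 2 instruments")
  est <- mr_ivw(h, model = "fixed")
  list(q = est$q, df = est$q_df, pval = est$q_pval)
}

#' Tidy report table for a set of MR estimates
#'
#' One row per estimate with all `mr_estimate` fields; when the outcome is
#' binary (log-odds scale) the odds ratio and its 95% CI are appended as
#' presentation columns.
#'
#' @param estimates a list of [mr_estimate()] objects.
#' @return data frame.
#' @export
mr_report <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  binary <- vapply(estimates, function(e) e$outcome_type == "binary-logodds",
                   logical(1))
  # OR columns are always present so report schemas are stable across
  # binary and continuous outcomes; NA when the scale is not log-odds
  tab$or <- ifelse(binary, exp(tab$beta), NA_real_)
  tab$or_ci_low <- ifelse(binary, exp(tab$ci_low), NA_real_)
  tab$or_ci_high <- ifelse(binary, exp(tab$ci_high), NA_real_)
  rownames(tab) <- NULL
  tab
}
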