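# Regression-based multivariable MR: conditional effects, MVMR-Egger,
# conditional instrument strength.

#' Construct an MVMR result
#'
#' Per-exposure conditional estimates from a joint weighted regression of
#' SNP-outcome effects on K SNP-exposure effect columns.
#'
#' @param exposures ordered exposure labels (K >= 2).
#' @param beta,se,pval per-exposure conditional estimates.
#' @param cond_f per-exposure conditional F statistics (may be `NA`).
#' @param n_snp number of instruments.
#' @param q,q_df,q_pval weighted residual heterogeneity.
#' @param egger_intercept,egger_intercept_se,egger_intercept_pval intercept
#'   triplet (MVMR-Egger only).
#' @param outcome,outcome_type outcome metadata.
#' @return An object of class `mvmr_result`.
#' @export
mvmr_result <- function(exposures, beta, se, pval, cond_f, n_snp,
                        q = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_pval = NA_real_,
                        outcome = NA_character_,
                        outcome_type = "continuous") {
  if (length(exposures) < 2L) config_error("MVMR requires K >= 2 exposures")
  if (any(se <= 0, na.rm = TRUE)) input_error("all MVMR SEs must be > 0")
  structure(list(exposures = exposures,
                 beta = stats::setNames(beta, exposures),
                 se = stats::setNames(se, exposures),
                 ci_low = stats::setNames(beta - z95() * se, exposures),
                 ci_high = stats::setNames(beta + z95() * se, exposures),
                 pval = stats::setNames(pval, exposures),
                 cond_f = stats::setNames(cond_f, exposures),
                 n_snp = n_snp, q = q, q_df = q_df, q_pval = q_pval,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_pval = egger_intercept_pval,
                 outcome = outcome, outcome_type = outcome_type),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %s ~ %s (%d SNPs)\n", x$outcome,
              paste(x$exposures, collapse = " + "), x$n_snp))
  print(as.data.frame(x))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  intercept = %.4f (SE %.4f, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  invisible(x)
}

#' @export
as.data.frame.mvmr_result <- function(x, ...) {
  tab <- data.frame(exposure = x$exposures, outcome = x$outcome,
                    beta = unname(x$beta), se = unname(x$se),
                    ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
                    pval = unname(x$pval), cond_f = unname(x$cond_f),
                    n_snp = x$n_snp, stringsAsFactors = FALSE)
  if (identical(x$outcome_type, "binary-logodds")) {
    tab$or <- exp(tab$beta)
    tab$or_ci_low <- exp(tab$ci_low)
    tab$or_ci_high <- exp(tab$ci_high)
  }
  rownames(tab) <- NULL
  tab
}

# exposure columns that are exactly zero carry no information at all;
# they are excluded from the fit (estimate NA) instead of tripping the
# rank check, matching lm()'s treatment of aliased terms
zero_exposure_cols <- function(h) colSums(abs(h$exposure_beta)) == 0

check_mvmr_design <- function(h, extra_df = 0L) {
  K <- n_exposures(h)
  n <- n_snps(h)
  if (K < 2L) config_error("MVMR requires at least two exposures")
  if (n < K + 1L + extra_df)
    input_error(sprintf("MVMR needs at least %d SNPs for %d exposures, got %d",
                        K + 1L + extra_df, K, n))
  Xw <- h$exposure_beta[, !zero_exposure_cols(h), drop = FALSE] / h$outcome_se
  kap <- kappa(Xw, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8) {
    cors <- suppressWarnings(stats::cor(Xw))
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    collin_error(sprintf(
      "collinear exposure beta columns (condition number %.3g); worst pair: %s, %s",
      kap, h$exposures[worst[1]], h$exposures[worst[2]]))
  }
  invisible(TRUE)
}

#' Multivariable IVW MR
#'
#' Weighted least squares (no intercept, weights `1/outcome_se^2`) of
#' SNP-outcome effects on the K SNP-exposure effect columns over the union of
#' the exposures' instruments. Each coefficient is the conditional (direct)
#' effect of that exposure given the others. SEs use multiplicative residual
#' scaling floored at 1.
#'
#' @param h a [harmonised_set()] with K >= 2 exposures and at least K+1 SNPs.
#' @param cond_f compute per-exposure conditional F statistics (default TRUE).
#' @return An [mvmr_result()].
#' @export
mvmr_ivw <- function(h, cond_f = TRUE) {
  stopifnot(inherits(h, "harmonised_set"))
  check_mvmr_design(h)
  n <- n_snps(h); K <- n_exposures(h)
  zero <- zero_exposure_cols(h)
  w <- 1 / h$outcome_se^2
  fit <- wls_fit(h$exposure_beta[, !zero, drop = FALSE], h$outcome_beta, w)
  q_df <- n - sum(!zero)
  scale <- sqrt(max(fit$rss / q_df, 1))
  coefs <- ses <- rep(NA_real_, K)
  coefs[!zero] <- fit$coef
  ses[!zero] <- sqrt(diag(fit$vcov_fixed)) * scale
  fs <- if (cond_f) vapply(seq_len(K), function(k)
    if (zero[k]) 0 else conditional_f(h, k), numeric(1))
    else rep(NA_real_, K)
  mvmr_result(h$exposures, coefs, ses, z_pval(coefs, ses), fs, n,
              q = fit$rss, q_df = q_df,
              q_pval = stats::pchisq(fit$rss, q_df, lower.tail = FALSE),
              outcome = h$outcome, outcome_type = h$outcome_type)
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] but with an intercept term, after orienting all SNPs to a
#' non-negative beta on the first-listed exposure. A non-zero intercept
#' indicates directional pleiotropy not absorbed by the included exposures.
#'
#' @param h a [harmonised_set()] with K >= 2 exposures and at least K+2 SNPs.
#' @return An [mvmr_result()] with the intercept triplet filled in.
#' @export
mvmr_egger <- function(h) {
  stopifnot(inherits(h, "harmonised_set"))
  check_mvmr_design(h, extra_df = 1L)
  h <- orient_positive(h, 1L)
  n <- n_snps(h); K <- n_exposures(h)
  w <- 1 / h$outcome_se^2
  fit <- wls_fit(cbind(`(intercept)` = 1, h$exposure_beta), h$outcome_beta, w)
  q_df <- n - K - 1L
  scale <- sqrt(max(fit$rss / q_df, 1))
  ses <- sqrt(diag(fit$vcov_fixed)) * scale
  mvmr_result(h$exposures, fit$coef[-1], ses[-1],
              z_pval(fit$coef[-1], ses[-1]), rep(NA_real_, K), n,
              q = fit$rss, q_df = q_df,
              q_pval = stats::pchisq(fit$rss, q_df, lower.tail = FALSE),
              egger_intercept = fit$coef[1], egger_intercept_se = ses[1],
              egger_intercept_pval = z_pval(fit$coef[1], ses[1]),
              outcome = h$outcome, outcome_type = h$outcome_type)
}

#' Conditional instrument strength (summary-data conditional F)
#'
#' Measures how much instrument signal remains in one exposure's SNP-effect
#' column after projecting out the other exposures' columns: the target
#' column is regressed on the others (weights `1/outcome_se^2`, no
#' intercept), each residual is scaled by the target exposure's own SE, and
#' `F = sum(resid^2 / se^2) / (n_snp - K + 1)`. Values near or below 1
#' indicate the exposure carries no independent instrument signal; the
#' conventional adequacy threshold is F > 10. Perfectly collinear exposure
#' columns return 0 with a warning.
#'
#' @param h a [harmonised_set()] with K >= 2 exposures and n_snp > K.
#' @param exposure exposure index or label.
#' @return nonnegative scalar (larger = stronger).
#' @export
conditional_f <- function(h, exposure) {
  stopifnot(inherits(h, "harmonised_set"))
  K <- n_exposures(h); n <- n_snps(h)
  if (K < 2L) config_error("conditional_f requires K >= 2 exposures")
  if (n <= K) input_error("conditional_f requires n_snp > K")
  k <- if (is.character(exposure)) match(exposure, h$exposures) else exposure
  if (is.na(k) || k < 1L || k > K) config_error("unknown exposure")
  target <- h$exposure_beta[, k]
  others <- h$exposure_beta[, -k, drop = FALSE]
  w <- 1 / h$outcome_se^2
  resid <- tryCatch({
    fit <- wls_fit(others, target, w)
    target - as.numeric(others %*% fit$coef)
  }, twostepmr_collinearity_error = function(e) target - target)
  strength <- sum(resid^2 / h$exposure_se[, k]^2)
  if (strength < 1e-10 * sum(target^2 / h$exposure_se[, k]^2 + 1)) {
    warning(sprintf("conditional_f: exposure %s is collinear with the others",
                    h$exposures[k]))
    return(0)
  }
  strength / (n - K + 1L)
}

#' Direct effect of the primary exposure given a mediator set
#'
#' Convenience projection: with mediators present this is the primary
#' exposure's conditional coefficient from [mvmr_ivw()]; with an empty
#' mediator set it degenerates to the univariable IVW total effect.
#'
#' @param h a [harmonised_set()] whose first exposure is the primary exposure
#'   and remaining exposures are the mediator set (possibly none).
#' @param ... passed to [mr_ivw()] in the degenerate single-exposure case.
#' @return An [mr_estimate()] with method `"mvmr-direct"` (or the univariable
#'   IVW estimate when no mediators are present).
#' @export
direct_effect <- function(h, ...) {
  stopifnot(inherits(h, "harmonised_set"))
  if (n_exposures(h) == 1L) return(mr_ivw(h, ...))
  res <- mvmr_ivw(h, cond_f = FALSE)
  mr_estimate("mvmr-direct", res$beta[[1]], res$se[[1]], res$n_snp,
              q = res$q, q_df = res$q_df, q_pval = res$q_pval,
              exposure = h$exposures[1], outcome = h$outcome,
              outcome_type = h$outcome_type)
}
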