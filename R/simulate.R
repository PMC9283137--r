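# Seeded synthetic GWAS generator: individual-level cohorts under a known
# exposure -> mediators -> binary outcome causal model, plus per-SNP summary
# statistics, with ground truth for every estimand.

#' Simulation configuration
#'
#' Describes a generative model with independent biallelic SNPs instrumenting
#' a standardised continuous exposure (variance ~1) and K continuous
#' mediators, and a binary outcome generated through a logistic link so that
#' all true outcome-scale effects live on log-odds. Three (by default
#' disjoint) cohorts emulate the two-sample design: one per GWAS of the
#' exposure, the mediators, and the outcome.
#'
#' Structural model, per individual (`U` a standard-normal confounder):
#' `M_base_j = G_j gamma_j + c_m U + e_mj` (variance 1),
#' `EA = G_ea beta + sum_j reverse_beta_j M_base_j + c_e U + e_e`,
#' `M_j = M_base_j + alpha_j EA + sum_{i<j} med_on_med[j,i] M_i`,
#' `logit P(Y=1) = b0 + direct EA + sum_j theta_j M_j + c_y U + G p`,
#' with `b0` solved by bisection so the outcome cohort hits
#' `outcome_prevalence`, and `p` optional per-SNP pleiotropic effects.
#'
#' Defaults form the desk-scale preset: 20,000 individuals per cohort and an
#' instrument-strength-preserving scaled-down SNP panel (25 exposure SNPs at
#' h2 = 0.11, 20 SNPs per mediator at h2 = 0.10), giving mean per-instrument
#' F statistics near those of the large source GWAS the structure emulates.
#' Effect defaults mirror a BMI-like single-mediator model: `alpha = -0.34`,
#' `theta = log(2.60)`, total effect `log(0.53)` on log-odds, 8% outcome
#' prevalence.
#'
#' @param seed RNG seed; identical configs give byte-identical output.
#' @param n_exposure_sample,n_mediator_sample,n_outcome_sample cohort sizes.
#' @param m_ea_snps,m_med_snps SNP counts for the exposure and per mediator.
#' @param maf_range uniform range of minor-allele frequencies.
#' @param h2_ea,h2_med variance explained by each trait's SNPs (exactly
#'   enforced given realised MAFs); `h2_med` is recycled over mediators.
#' @param alpha named vector of exposure->mediator effects (names label the
#'   mediators).
#' @param theta mediator->outcome log-odds effects (same names as `alpha`).
#' @param direct exposure->outcome direct log-odds effect.
#' @param conf_strength confounder loadings `c(exposure, mediator, outcome)`.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"` direct
#'   SNP->outcome effects on a fraction of exposure SNPs.
#' @param pleiotropy_magnitude mean (directional) or SD (balanced) of the
#'   pleiotropic log-odds effects.
#' @param pleiotropy_fraction fraction of exposure SNPs affected.
#' @param outcome_prevalence target case fraction in the outcome cohort.
#' @param reverse_beta mediator->exposure effect(s) for bidirectionality
#'   scenarios (recycled over mediators; default 0).
#' @param med_on_med optional K-by-K lower-triangular matrix of
#'   mediator-on-mediator effects (row j receives column i < j), for
#'   overlapping-mediator scenarios.
#' @param overlap if `TRUE`, the outcome GWAS reuses the exposure cohort
#'   (deliberate sample overlap, to study the associated bias).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_exposure_sample = 20000L,
                       n_mediator_sample = 20000L,
                       n_outcome_sample = 20000L,
                       m_ea_snps = 25L, m_med_snps = 20L,
                       maf_range = c(0.1, 0.5),
                       h2_ea = 0.11, h2_med = 0.10,
                       alpha = c(BMI = -0.34),
                       theta = c(BMI = log(2.60)),
                       direct = log(0.53) - sum(alpha * theta),
                       conf_strength = c(exposure = 0.2, mediator = 0.2,
                                         outcome = 0.2),
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_magnitude = 0.08,
                       pleiotropy_fraction = 0.3,
                       outcome_prevalence = 0.08,
                       reverse_beta = 0,
                       med_on_med = NULL,
                       overlap = FALSE) {
  pleiotropy <- match.arg(pleiotropy)
  K <- length(alpha)
  if (is.null(names(alpha))) names(alpha) <- paste0("M", seq_len(K))
  if (length(theta) != K)
    config_error("`alpha` and `theta` must have one entry per mediator")
  names(theta) <- names(alpha)
  h2_med <- rep_len(h2_med, K)
  reverse_beta <- rep_len(reverse_beta, K)
  if (length(conf_strength) != 3L) config_error("`conf_strength` needs 3 loadings")
  names(conf_strength) <- c("exposure", "mediator", "outcome")
  if (h2_ea < 0 || h2_ea > 1 || any(h2_med < 0 | h2_med > 1))
    config_error("heritabilities must lie in [0,1]")
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1)
    config_error("outcome_prevalence must lie in (0,1)")
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
    config_error("maf_range must be within (0,1)")
  if (h2_ea + conf_strength[["exposure"]]^2 + sum(reverse_beta^2) > 1)
    config_error("exposure variance budget exceeds 1 (h2 + confounding + reverse)")
  if (any(h2_med + conf_strength[["mediator"]]^2 > 1))
    config_error("mediator variance budget exceeds 1 (h2 + confounding)")
  if (!is.null(med_on_med)) {
    med_on_med <- as.matrix(med_on_med)
    if (!identical(dim(med_on_med), c(K, K)) ||
        any(med_on_med[upper.tri(med_on_med, diag = TRUE)] != 0))
      config_error("med_on_med must be K x K strictly lower triangular")
  }
  structure(list(seed = as.integer(seed),
                 n_exposure_sample = as.integer(n_exposure_sample),
                 n_mediator_sample = as.integer(n_mediator_sample),
                 n_outcome_sample = as.integer(n_outcome_sample),
                 m_ea_snps = as.integer(m_ea_snps),
                 m_med_snps = as.integer(m_med_snps),
                 maf_range = maf_range, h2_ea = h2_ea, h2_med = h2_med,
                 alpha = alpha, theta = theta, direct = direct,
                 conf_strength = conf_strength, pleiotropy = pleiotropy,
                 pleiotropy_magnitude = pleiotropy_magnitude,
                 pleiotropy_fraction = pleiotropy_fraction,
                 outcome_prevalence = outcome_prevalence,
                 reverse_beta = reverse_beta, med_on_med = med_on_med,
                 overlap = overlap),
            class = "sim_config")
}

# scale raw effects so sum(2 p (1-p) b^2) over the trait's SNPs equals h2
scale_to_h2 <- function(raw, maf, h2) {
  if (h2 == 0 || !length(raw)) return(raw * 0)
  v <- sum(2 * maf * (1 - maf) * raw^2)
  raw * sqrt(h2 / v)
}

# draw the SNP panel (MAFs, per-trait effect vectors, pleiotropy); truth is
# fully determined here
draw_sim_params <- function(cfg) {
  K <- length(cfg$alpha)
  m <- cfg$m_ea_snps + K * cfg$m_med_snps
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  snp <- paste0("rs", seq_len(m))
  block <- c(rep("EA", cfg$m_ea_snps),
             rep(names(cfg$alpha), each = cfg$m_med_snps))
  beta_ea <- numeric(m)
  idx_ea <- which(block == "EA")
  beta_ea[idx_ea] <- scale_to_h2(stats::rnorm(cfg$m_ea_snps), maf[idx_ea],
                                 cfg$h2_ea)
  gamma <- matrix(0, m, K, dimnames = list(snp, names(cfg$alpha)))
  for (j in seq_len(K)) {
    idx <- which(block == names(cfg$alpha)[j])
    gamma[idx, j] <- scale_to_h2(stats::rnorm(cfg$m_med_snps), maf[idx],
                                 cfg$h2_med[j])
  }
  pleio <- numeric(m)
  if (cfg$pleiotropy != "none") {
    n_pl <- max(1L, round(cfg$pleiotropy_fraction * cfg$m_ea_snps))
    which_pl <- sample(idx_ea, n_pl)
    # directional = positive mean on the exposure-increasing allele, the
    # frame in which the Egger intercept is interpreted
    pleio[which_pl] <- if (cfg$pleiotropy == "directional")
      sign(beta_ea[which_pl]) *
        stats::rnorm(n_pl, cfg$pleiotropy_magnitude,
                     cfg$pleiotropy_magnitude / 4)
    else stats::rnorm(n_pl, 0, cfg$pleiotropy_magnitude)
  }
  list(snp = data.frame(snp = snp, block = block, maf = maf, ea = "A",
                        oa = "G", stringsAsFactors = FALSE),
       beta_ea = beta_ea, gamma = gamma, pleio = pleio)
}

sim_one_sample <- function(cfg, params, n, b0 = NULL) {
  K <- length(cfg$alpha)
  m <- nrow(params$snp)
  G <- matrix(stats::rbinom(n * m, 2L, rep(params$snp$maf, each = n)), n, m)
  colnames(G) <- params$snp$snp
  U <- stats::rnorm(n)
  cs <- cfg$conf_strength
  m_base <- matrix(0, n, K)
  for (j in seq_len(K)) {
    e_var <- 1 - cfg$h2_med[j] - cs[["mediator"]]^2
    m_base[, j] <- as.numeric(G %*% params$gamma[, j]) +
      cs[["mediator"]] * U + stats::rnorm(n, 0, sqrt(max(e_var, 1e-8)))
  }
  e_var_ea <- 1 - cfg$h2_ea - cs[["exposure"]]^2 - sum(cfg$reverse_beta^2)
  ea <- as.numeric(G %*% params$beta_ea) +
    as.numeric(m_base %*% cfg$reverse_beta) +
    cs[["exposure"]] * U + stats::rnorm(n, 0, sqrt(max(e_var_ea, 1e-8)))
  med <- matrix(0, n, K, dimnames = list(NULL, names(cfg$alpha)))
  for (j in seq_len(K)) {
    med[, j] <- m_base[, j] + cfg$alpha[j] * ea
    if (!is.null(cfg$med_on_med) && j > 1L)
      med[, j] <- med[, j] +
        med[, seq_len(j - 1L), drop = FALSE] %*% cfg$med_on_med[j, seq_len(j - 1L)]
  }
  eta0 <- cfg$direct * ea + as.numeric(med %*% cfg$theta) +
    cs[["outcome"]] * U + as.numeric(G %*% params$pleio)
  if (is.null(b0))
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) -
                           cfg$outcome_prevalence,
                         lower = -50, upper = 50, tol = 1e-10)$root
  outcome <- stats::rbinom(n, 1L, stats::plogis(b0 + eta0))
  dat <- data.frame(ea = ea, U = U, outcome = outcome)
  dat[colnames(med)] <- as.data.frame(med)
  list(G = G, data = dat, snp = params$snp, b0 = b0)
}

#' Simulate the full multi-cohort study
#'
#' Draws the SNP panel and effect sizes once, then simulates the exposure,
#' mediator, and outcome cohorts independently from the same generative
#' parameters (the two-sample structure). The logistic intercept is solved by
#' bisection on the outcome cohort so its expected case fraction equals the
#' configured prevalence. Everything flows from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `samples` (named list of cohorts, each holding a
#'   genotype matrix `G` and a phenotype frame `data`), `params`, and
#'   `truth` (a `sim_truth`, see below).
#'
#' @section Truth:
#' `truth` contains the structural `alpha`, `theta`, `direct`; the path
#' coefficients `path_alpha` (`dM_j/dEA`, solving the mediator chain);
#' per-mediator `indirect = theta_j * path_alpha_j`; `total = direct +
#' sum(indirect)`; per-mediator and combined proportions mediated; and the
#' per-SNP effect tables with instrument id lists per trait. The identity
#' `total = direct + sum(indirect)` holds exactly on the log-odds scale.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    params <- draw_sim_params(cfg)
    outcome_s <- sim_one_sample(cfg, params, cfg$n_outcome_sample)
    b0 <- outcome_s$b0
    exposure_s <- sim_one_sample(cfg, params, cfg$n_exposure_sample, b0 = b0)
    mediator_s <- sim_one_sample(cfg, params, cfg$n_mediator_sample, b0 = b0)
    K <- length(cfg$alpha)
    path_alpha <- numeric(K)
    for (j in seq_len(K)) {
      path_alpha[j] <- cfg$alpha[j]
      if (!is.null(cfg$med_on_med) && j > 1L)
        path_alpha[j] <- path_alpha[j] +
          sum(cfg$med_on_med[j, seq_len(j - 1L)] * path_alpha[seq_len(j - 1L)])
    }
    names(path_alpha) <- names(cfg$alpha)
    indirect <- cfg$theta * path_alpha
    total <- cfg$direct + sum(indirect)
    truth <- structure(list(
      total = total, direct = cfg$direct, indirect = indirect,
      pm = indirect / total, combined_pm = sum(indirect) / total,
      alpha = cfg$alpha, theta = cfg$theta, path_alpha = path_alpha,
      b0 = b0, prevalence = cfg$outcome_prevalence,
      snp_effects = {
        gm <- as.data.frame(params$gamma)
        names(gm) <- paste0("gamma_", names(gm))
        cbind(data.frame(params$snp, beta_ea = params$beta_ea,
                         stringsAsFactors = FALSE),
              gm, pleio = params$pleio)
      },
      instruments = c(list(EA = params$snp$snp[params$snp$block == "EA"]),
                      stats::setNames(
                        lapply(names(cfg$alpha), function(l)
                          params$snp$snp[params$snp$block == l]),
                        names(cfg$alpha)))),
      class = "sim_truth")
    list(samples = list(exposure = exposure_s, mediator = mediator_s,
                        outcome = outcome_s),
         params = params, truth = truth, cfg = cfg)
  })
}

# collapsed per-SNP logistic fit: with an allele-count covariate g in
# {0,1,2} the MLE depends only on the 3x2 table, so Newton-Raphson on the
# cell counts reproduces the full logistic regression exactly
logistic_snp_fit <- function(n_g, k_g, max_iter = 25L, tol = 1e-8) {
  g <- 0:2
  keep <- n_g > 0
  if (sum(keep) < 2L || sum(k_g) == 0L || sum(k_g) == sum(n_g))
    return(NULL)
  p0 <- sum(k_g) / sum(n_g)
  par <- c(log(p0 / (1 - p0)), 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- par[1] + par[2] * g
    mu <- stats::plogis(eta)
    wgt <- n_g * mu * (1 - mu)
    grad <- c(sum(k_g - n_g * mu), sum(g * (k_g - n_g * mu)))
    H <- matrix(c(sum(wgt), sum(g * wgt), sum(g * wgt), sum(g^2 * wgt)), 2, 2)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    par <- par + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- par[1] + par[2] * g
  mu <- stats::plogis(eta)
  wgt <- n_g * mu * (1 - mu)
  H <- matrix(c(sum(wgt), sum(g * wgt), sum(g * wgt), sum(g^2 * wgt)), 2, 2)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc)) return(NULL)
  list(beta = par[2], se = sqrt(vc[2, 2]), converged = converged)
}

#' Per-SNP GWAS summary statistics from a simulated cohort
#'
#' Continuous traits: simple linear regression of the trait on allele count,
#' per SNP (vectorised closed form). Binary traits: per-SNP logistic
#' regression Wald fit via Newton-Raphson on the collapsed genotype-by-case
#' table (iteration cap 25, tolerance 1e-8; non-converged SNPs are flagged
#' in the `"nonconverged"` attribute). Optional covariate adjustment
#' residualises a continuous trait on the named columns first, emulating
#' e.g. BMI-adjusted blood-pressure GWAS.
#'
#' @param sample one cohort from [simulate_cohort()] (`$samples$...`).
#' @param trait column of `sample$data` to analyse.
#' @param trait_type `"continuous"` or `"binary-logodds"` (guessed from the
#'   data when missing).
#' @param trait_label,unit metadata for the resulting [summary_stats()].
#' @param adjust_for optional character vector of `sample$data` columns to
#'   residualise a continuous trait on.
#' @return A [summary_stats()] object; non-varying SNPs are skipped with a
#'   message.
#' @export
gwas_summarise <- function(sample, trait, trait_type = NULL,
                           trait_label = trait, unit = NA_character_,
                           adjust_for = NULL) {
  if (!trait %in% names(sample$data))
    config_error(sprintf("trait `%s` not present in sample", trait))
  y <- sample$data[[trait]]
  G <- sample$G
  n <- length(y)
  trait_type <- trait_type %||%
    (if (all(y %in% c(0, 1))) "binary-logodds" else "continuous")
  varying <- apply(G, 2, function(g) stats::var(g) > 0)
  if (!all(varying))
    message(sprintf("gwas_summarise: skipped %d non-varying SNP(s)",
                    sum(!varying)))
  G <- G[, varying, drop = FALSE]
  snp_meta <- sample$snp[varying, , drop = FALSE]
  eaf <- colMeans(G) / 2
  nonconv <- character(0)
  if (trait_type == "continuous") {
    if (!is.null(adjust_for)) {
      y <- stats::residuals(stats::lm(
        stats::reformulate(adjust_for, response = trait), data = sample$data))
    }
    yc <- y - mean(y)
    Gc <- sweep(G, 2, colMeans(G))
    sxx <- colSums(Gc^2)
    sxy <- colSums(Gc * yc)
    beta <- sxy / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    pval <- 2 * stats::pt(abs(beta / se), n - 2, lower.tail = FALSE)
  } else {
    if (!is.null(adjust_for))
      config_error("covariate adjustment is only supported for continuous traits")
    cases <- y == 1
    beta <- se <- rep(NA_real_, ncol(G))
    for (j in seq_len(ncol(G))) {
      n_g <- tabulate(G[, j] + 1L, 3L)
      k_g <- tabulate(G[cases, j] + 1L, 3L)
      fit <- logistic_snp_fit(n_g, k_g)
      if (is.null(fit)) { nonconv <- c(nonconv, snp_meta$snp[j]); next }
      if (!fit$converged) nonconv <- c(nonconv, snp_meta$snp[j])
      beta[j] <- fit$beta; se[j] <- fit$se
    }
    ok <- !is.na(beta)
    G <- G[, ok, drop = FALSE]; snp_meta <- snp_meta[ok, , drop = FALSE]
    beta <- beta[ok]; se <- se[ok]; eaf <- eaf[ok]
    pval <- z_pval(beta, se)
  }
  out <- summary_stats(
    data.frame(snp = snp_meta$snp, ea = snp_meta$ea, oa = snp_meta$oa,
               eaf = eaf, beta = beta, se = se,
               pval = pmax(pval, .Machine$double.xmin), n = n,
               stringsAsFactors = FALSE),
    trait_label = trait_label, trait_type = trait_type, unit = unit)
  attr(out, "nonconverged") <- nonconv
  out
}

#' Build a complete two-sample GWAS scenario
#'
#' Runs [simulate_cohort()] and summarises each trait's GWAS on its own
#' cohort: the exposure on the exposure cohort, every mediator on the
#' mediator cohort, and the binary outcome on the outcome cohort (or on the
#' exposure cohort when `cfg$overlap` is set, to emulate sample overlap).
#' All GWAS report all SNPs, as the MVMR steps require.
#'
#' @param cfg a [sim_config()].
#' @param keep_cohort retain the individual-level cohorts in the result
#'   (default `FALSE`; they are large).
#' @return list with `stats` (elements `exposure`, `mediators` — a named
#'   list — and `outcome`, all [summary_stats()]), `truth`, and optionally
#'   `cohort`.
#' @export
make_two_sample_scenario <- function(cfg, keep_cohort = FALSE) {
  cohort <- simulate_cohort(cfg)
  meds <- names(cfg$alpha)
  stats_ <- list(
    exposure = gwas_summarise(cohort$samples$exposure, "ea",
                              trait_type = "continuous", trait_label = "EA",
                              unit = "SD (4.2 years)"),
    mediators = stats::setNames(lapply(meds, function(mlab)
      gwas_summarise(cohort$samples$mediator, mlab,
                     trait_type = "continuous", trait_label = mlab,
                     unit = "SD")), meds),
    outcome = gwas_summarise(
      if (cfg$overlap) cohort$samples$exposure else cohort$samples$outcome,
      "outcome", trait_type = "binary-logodds", trait_label = "T2D",
      unit = "log-odds"))
  out <- list(stats = stats_, truth = cohort$truth, cfg = cfg)
  if (keep_cohort) out$cohort <- cohort
  out
}
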