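# Independent oracles and fixture builders used across test files.

# weighted least squares oracle through stats::lm (independent of the
# package's QR route); returns coefficients and both SE conventions
oracle_wls <- function(X, y, w, intercept = FALSE) {
  df <- data.frame(y = y, X)
  form <- if (intercept) y ~ . else y ~ . - 1
  fit <- stats::lm(form, data = df, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  se_model <- sm$coefficients[, 2]
  list(coef = unname(stats::coef(fit)),
       se_fixed = unname(se_model / sigma),
       se_scaled = unname(se_model / sigma * max(1, sigma)),
       rss = sum(w * stats::residuals(fit)^2))
}

# brute-force cumulative-weight interpolation oracle for the weighted median
oracle_weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  x <- cumsum(w) - w / 2
  if (0.5 <= x[1]) return(b[1])
  if (0.5 >= x[length(x)]) return(b[length(b)])
  stats::approx(x, b, xout = 0.5)$y
}

# independent greedy-clumping reference: plain loops over a full r2 matrix
oracle_greedy_clump <- function(snp, pval, pos, r2mat, p_threshold,
                                r2_threshold, window) {
  keep <- which(pval < p_threshold)
  ord <- keep[order(pval[keep], snp[keep])]
  selected <- character(0)
  removed <- character(0)
  for (i in ord) {
    if (snp[i] %in% removed) next
    selected <- c(selected, snp[i])
    for (j in ord) {
      if (j == i || snp[j] %in% removed || snp[j] %in% selected) next
      within <- if (is.na(pos[i]) || is.na(pos[j])) TRUE
                else abs(pos[i] - pos[j]) <= window
      if (within && r2mat[snp[i], snp[j]] >= r2_threshold)
        removed <- c(removed, snp[j])
    }
  }
  sort(selected)
}

# minimal valid summary-stat record frame
toy_records <- function(n = 3L, seed = 1L, palindromic = FALSE) {
  withr::with_seed(seed, {
    data.frame(snp = paste0("rs", seq_len(n)),
               chr = "1", pos = seq_len(n) * 1e5,
               ea = if (palindromic) "A" else "A",
               oa = if (palindromic) "T" else "G",
               eaf = runif(n, 0.1, 0.45),
               beta = rnorm(n, 0, 0.05),
               se = runif(n, 0.005, 0.02),
               pval = runif(n, 1e-12, 1e-9),
               n = 10000, stringsAsFactors = FALSE)
  })
}

toy_ss <- function(n = 3L, seed = 1L, label = "EA", ...) {
  summary_stats(toy_records(n, seed, ...), trait_label = label)
}

# harmonised set straight from effect vectors (already aligned)
make_h <- function(bx, by, sx = rep(0.01, length(by)),
                   sy = rep(0.05, length(by)), K = 1L,
                   outcome_type = "continuous") {
  harmonised_set(paste0("rs", seq_along(by)), bx, sx, by, sy,
                 outcome_type = outcome_type)
}

# random noisy instance with K exposure columns
random_h <- function(n, K = 1L, seed = 1L, outcome_type = "continuous") {
  withr::with_seed(seed, {
    bx <- matrix(rnorm(n * K, 0, 0.1), n, K,
                 dimnames = list(NULL, paste0("X", seq_len(K))))
    sx <- matrix(runif(n * K, 0.003, 0.01), n, K)
    theta <- seq(0.2, 0.6, length.out = K)
    sy <- runif(n, 0.02, 0.08)
    by <- as.numeric(bx %*% theta) + rnorm(n, 0, sy)
    harmonised_set(paste0("rs", seq_len(n)), bx, sx, by, sy,
                   outcome_type = outcome_type)
  })
}

# summary-level homogeneous two-sample draw: true per-SNP exposure effects
# gx, outcome betas theta*gx + N(0, sy); tiny exposure-side noise
draw_null_h <- function(m = 30L, theta = 0.3, sy = 0.05, sx = 1e-4) {
  gx <- rnorm(m, 0, 0.1)
  gx <- gx + sign(gx) * 0.05              # keep instruments relevant
  bx <- gx + rnorm(m, 0, sx)
  by <- theta * gx + rnorm(m, 0, sy)
  harmonised_set(paste0("rs", seq_len(m)), bx, rep(sx, m), by, rep(sy, m))
}

# subset a summary_stats to an instrument id list (attribute-preserving)
restrict_snps_for_test <- function(ss, ids) ss[ss$snp %in% ids, , drop = FALSE]
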