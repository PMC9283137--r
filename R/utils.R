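# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# 95% normal quantile used for all CIs (summary-data asymptotics, not t)
z95 <- function() stats::qnorm(0.975)

stop_tsmr <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "twostepmr_error", "error", "condition")))
}

config_error  <- function(msg) stop_tsmr(msg, "twostepmr_config_error")
input_error   <- function(msg) stop_tsmr(msg, "twostepmr_input_error")
overlap_error <- function(msg) stop_tsmr(msg, "twostepmr_no_overlap_error")
collin_error  <- function(msg) stop_tsmr(msg, "twostepmr_collinearity_error")

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

# two-sided normal p-value for an estimate/SE pair
z_pval <- function(beta, se) 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
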