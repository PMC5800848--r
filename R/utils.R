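# Shared numerical helpers.

# z-scores are clamped where a normal quantile would overflow double
# precision; 8.2 is comfortably inside qnorm's accurate range.
Z_CLAMP <- 8.2

clamp_z <- function(z, clamp = Z_CLAMP) {
  pmin(pmax(z, -clamp), clamp)
}

# Upper-tail normal quantile of p computed stably from log(p).
qnorm_upper_log <- function(log_p) {
  stats::qnorm(log_p, lower.tail = FALSE, log.p = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
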