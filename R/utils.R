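# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

#' @noRd
# Clamp a probability vector into [lo, 1 - lo]; used where a log-link
# linear predictor can stray above 0 in a simulation draw.
clamp01 <- function(p, lo = 0) pmin(pmax(p, lo), 1 - lo)

# Derive a reproducible child seed (< 2^31) from a base seed and an index.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

# Two-sided simulation p-value from a vector of draws.
tail_pvalue <- function(draws) {
  min(1, 2 * min(mean(draws <= 0), mean(draws >= 0)))
}

# Percentile CI from draws.
pct_ci <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), na.rm = TRUE, names = FALSE))
}

# Weighted average of the two conditional effects; weights are the arm
# proportions (w1 for the intervention group).
avg_conditional <- function(e0, e1, w0, w1) w0 * e0 + w1 * e1
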