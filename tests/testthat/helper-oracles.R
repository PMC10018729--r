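# Independent brute-force oracles, written without reference to the package
# implementation (or to stats::quantile / stats::cor), used to cross-check
# the rank statistics and order statistics.

# Linear interpolation between the closest order statistics.
oracle_percentile <- function(x, p = 0.05) {
  s <- sort(x)
  n <- length(s)
  if (n == 1) return(s)
  h <- (n - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[lo + 2 - (lo == n - 1)] - s[lo + 1])
}

# Average ranks by counting, then the Pearson product-moment formula.
oracle_rank <- function(v) {
  vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Toxic-unit ratio computed on the log scale, an arithmetically independent
# route to MEC[ng/L] * 1e-6 / EC50[mg/L].
oracle_tu <- function(mec_ng_L, ec50_mg_L) {
  exp(log(mec_ng_L) + log(1e-6) - log(ec50_mg_L))
}
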