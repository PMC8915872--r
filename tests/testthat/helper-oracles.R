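# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# Linear-interpolation quantile: index h = (n-1)*q + 1 between order stats.
oracle_quantile_linear <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Nearest-rank (inverse ECDF) quantile: smallest order statistic with
# ECDF >= q.
oracle_quantile_nearest <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  x[which(seq_len(n) / n >= q - 1e-12)[1]]
}

# Brute-force Tukey fences over explicit quartiles.
oracle_tukey <- function(values, quartile = "linear", k = 1.5) {
  if (length(values) == 1L) return(list(surviving = values, removed = numeric(0)))
  qf <- if (quartile == "linear") oracle_quantile_linear else oracle_quantile_nearest
  q1 <- qf(values, 0.25)
  q3 <- qf(values, 0.75)
  iqr <- q3 - q1
  keep <- values >= q1 - k * iqr & values <= q3 + k * iqr
  if (!any(keep)) keep <- rep(TRUE, length(values))
  list(surviving = values[keep], removed = values[!keep])
}

# Two-sample K-S D statistic by enumeration over all pooled points.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# All multisets (non-decreasing tuples) of lengths 1..maxlen over a grid.
all_multisets <- function(grid, maxlen) {
  out <- list()
  for (k in seq_len(maxlen)) {
    idx <- expand.grid(rep(list(seq_along(grid)), k))
    keep <- apply(idx, 1L, function(r) all(diff(as.numeric(r)) >= 0))
    m <- idx[keep, , drop = FALSE]
    out <- c(out, lapply(seq_len(nrow(m)),
                         function(i) grid[as.numeric(m[i, ])]))
  }
  out
}

# Small synthetic world used across tests.
make_synth <- function(n = 60, seed = 7, ...) {
  cfg <- synth_config(n_substances = n, seed = seed, ...)
  subs <- generate_substances(cfg)
  st <- generate_studies(subs, cfg)
  list(config = cfg, substances = subs, records = st$records,
       truth = st$truth)
}
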