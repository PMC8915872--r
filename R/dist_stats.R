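# Distributional machinery: log10 ECDFs, empirical percentiles, normal-CDF
# overlay, QQ data, Shapiro-Wilk, two-sample Kolmogorov-Smirnov, and the
# bootstrapped 5th percentile.

#' Empirical cumulative distribution on the log10 scale
#'
#' Sorts the (positive) values, log10-transforms them and attaches step
#' probabilities `p_i = i/n` at the i-th order statistic. Ties each occupy
#' their own order statistic.
#'
#' @param values Positive numeric vector.
#' @param log10_transform Transform to log10 first (default `TRUE`).
#' @return A list of class `ttc_ecdf` with `x` (sorted, possibly log10) and
#'   `p` (strictly increasing, ending at 1).
#' @export
ttc_ecdf <- function(values, log10_transform = TRUE) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (any(!is.finite(values)) || (log10_transform && any(values <= 0))) {
    stop("values must be finite and positive", call. = FALSE)
  }
  x <- sort(values)
  if (log10_transform) x <- log10(x)
  n <- length(x)
  structure(list(x = x, p = seq_len(n) / n), class = "ttc_ecdf")
}

#' Empirical percentile of a sample
#'
#' Computed on the raw value scale (log10 is used for plotting and
#' normality diagnostics only). `"linear"` interpolates between order
#' statistics (quantile type 7: index `1 + (n-1) p/100`); `"nearest"` is
#' the nearest-rank / inverse-ECDF estimator (type 1).
#'
#' @param values Numeric vector, n >= 1.
#' @param p Percentile level in (0, 100); default 5.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A list of class `percentile_estimate` with `value`, `p`, `n`,
#'   `method`.
#' @examples
#' empirical_percentile(1:100, 5)$value # 5.95
#' @export
empirical_percentile <- function(values, p = 5,
                                 method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 100) {
    stop("p must be a single percentile in (0, 100)", call. = FALSE)
  }
  type <- if (method == "linear") 7L else 1L
  v <- stats::quantile(values, p / 100, type = type, names = FALSE)
  structure(list(value = v, p = p, n = length(values), method = method),
            class = "percentile_estimate")
}

#' Normal-CDF overlay for an ECDF plot
#'
#' Fits a normal by moments to the log10 data and evaluates its CDF on a
#' regular grid spanning the data range, for overlaying on the empirical
#' CDF (the visual normality check).
#'
#' @param values Positive numeric vector, n >= 2 (log10 taken internally).
#' @param sample_n Number of evaluation points (default 1000).
#' @return Data.frame with `x` (log10 scale) and `cdf`.
#' @export
normal_overlay <- function(values, sample_n = 1000) {
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("values must be finite and positive", call. = FALSE)
  }
  lx <- log10(values)
  m <- mean(lx)
  s <- stats::sd(lx)
  if (s == 0) {
    warning("zero variance: degenerate overlay", call. = FALSE)
    s <- .Machine$double.eps
  }
  grid <- seq(min(lx), max(lx), length.out = sample_n)
  data.frame(x = grid, cdf = stats::pnorm(grid, mean = m, sd = s))
}

#' Normal quantile-quantile points
#'
#' Theoretical standard-normal quantiles at plotting positions
#' (`ppoints(n)`) paired with the sorted, standardized sample.
#'
#' @param values Numeric vector, n >= 3, non-constant.
#' @return Data.frame with `theoretical` and `sample` quantiles.
#' @export
qq_points <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance", call. = FALSE)
  data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
             sample = (sort(values) - mean(values)) / s)
}

#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk (Royston approximation), supported for
#' 3 <= n <= 5000.
#'
#' @param values Numeric vector.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk supports 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`, computed by direct enumeration over the
#' pooled jump points; the p-value uses the exact method when
#' `min(n_x, n_y) <= 25` and there are no ties across samples, the
#' asymptotic Kolmogorov distribution otherwise (the method actually used
#' is recorded).
#'
#' @param x,y Numeric samples, each n >= 1.
#' @return List with `D`, `p_value`, `method`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty",
                                             call. = FALSE)
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(fx - fy))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 25L && !ties
  p <- suppressWarnings(stats::ks.test(x, y, exact = exact)$p.value)
  list(D = D, p_value = p,
       method = if (exact) "exact" else "asymptotic",
       n_x = length(x), n_y = length(y))
}

#' Bootstrapped empirical percentile
#'
#' Resamples the values with replacement `n_replicates` times, computes the
#' percentile of each replicate with [empirical_percentile()], and reports
#' the median and central 95% interval of the replicate distribution.
#' Replicate r draws its own RNG stream from a seed derived
#' deterministically from `(seed, r)`, so results do not depend on how the
#' replicates might be scheduled.
#'
#' @inheritParams empirical_percentile
#' @param n_replicates Number of bootstrap replicates (default 10000).
#' @param seed Integer root seed.
#' @return A list of class `bootstrap_result` with `replicates`, `median`,
#'   `ci` (2.5% and 97.5% quantiles), `n_replicates`, `seed`, `p`,
#'   `method`.
#' @export
bootstrap_percentile <- function(values, p = 5, n_replicates = 10000,
                                 seed = 1, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("need n >= 2 to bootstrap", call. = FALSE)
  n <- length(values)
  type <- if (method == "linear") 7L else 1L
  # per-replicate seeds from one root stream; keep below 2^31
  rep_seeds <- withr_seed_streams(seed, n_replicates)
  reps <- vapply(seq_len(n_replicates), function(r) {
    set.seed(rep_seeds[r])
    stats::quantile(values[sample.int(n, n, replace = TRUE)],
                    p / 100, type = type, names = FALSE)
  }, numeric(1))
  structure(list(replicates = reps,
                 median = stats::median(reps),
                 ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
                 n_replicates = n_replicates, seed = seed, p = p,
                 method = method),
            class = "bootstrap_result")
}

# Derive n deterministic replicate seeds from a root seed (all < 2^31).
withr_seed_streams <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

#' Per-group distribution summary
#'
#' Convenience wrapper producing, for each group of values, the sample
#' size, the empirical 5th percentile, a bootstrapped 5th percentile when
#' requested, and normality diagnostics.
#'
#' @param values Positive numeric vector.
#' @param group Character/factor grouping vector of the same length.
#' @param p Percentile level (default 5).
#' @param bootstrap If `TRUE`, add bootstrap median and 95% interval.
#' @param n_replicates Bootstrap replicates.
#' @param seed Root seed for the bootstrap.
#' @param method Percentile method.
#' @return Data.frame with one row per group: `group`, `n`, `p5`,
#'   `boot_median`, `boot_lo`, `boot_hi`, `shapiro_W`, `shapiro_p`
#'   (Shapiro-Wilk on log10 values; `NA` when n outside 3..5000).
#' @export
group_distribution_summary <- function(values, group, p = 5,
                                       bootstrap = FALSE,
                                       n_replicates = 10000, seed = 1,
                                       method = "linear") {
  stopifnot(length(values) == length(group))
  sp <- split(values, group)
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    p5 <- empirical_percentile(v, p, method)$value
    bm <- blo <- bhi <- NA_real_
    if (bootstrap && length(v) >= 2L) {
      b <- bootstrap_percentile(v, p, n_replicates, seed, method)
      bm <- b$median; blo <- b$ci[1]; bhi <- b$ci[2]
    }
    sw <- if (length(v) >= 3L && length(v) <= 5000L && all(v > 0) &&
              stats::sd(log10(v)) > 0) {
      shapiro_wilk(log10(v))
    } else list(W = NA_real_, p_value = NA_real_)
    data.frame(group = g, n = length(v), p5 = p5,
               boot_median = bm, boot_lo = blo, boot_hi = bhi,
               shapiro_W = sw$W, shapiro_p = sw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
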