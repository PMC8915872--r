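# Collapse each substance's studies to one representative value:
# singletons retained, extreme outliers removed by Tukey fences, minimum
# taken per substance and unit track.

#' Tukey-fence outlier screening
#'
#' Removes values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` in a single pass.
#' A singleton input is always retained untouched. If removal would empty
#' the set, the original values are returned with a warning. Fencing is on
#' the raw value scale (logs enter the workflow only at the distribution
#' stage).
#'
#' @param values Numeric vector, non-empty, all positive.
#' @param quartile Quartile estimator: `"linear"` (interpolation between
#'   order statistics, the common statistics-environment default) or
#'   `"nearest"` (nearest rank).
#' @param tails `"both"` (the literal two-sided Tukey fence, default) or
#'   `"high"` to remove only high-tail outliers.
#' @param k Fence multiplier (default 1.5).
#' @return A list with `surviving` and `removed` numeric vectors and the
#'   `fences` used (`NA` for singletons).
#' @examples
#' tukey_fences(c(10, 10, 10, 10, 1000))$removed # 1000
#' tukey_fences(7.3)$surviving                   # singleton retained
#' @export
tukey_fences <- function(values, quartile = c("linear", "nearest"),
                         tails = c("both", "high"), k = 1.5) {
  quartile <- match.arg(quartile)
  tails <- match.arg(tails)
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("values must be finite and positive (clean upstream first)",
         call. = FALSE)
  }
  if (length(values) == 1L) {
    return(list(surviving = values, removed = numeric(0),
                fences = c(lower = NA_real_, upper = NA_real_)))
  }
  type <- if (quartile == "linear") 7L else 1L
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  out <- if (tails == "both") values < lower | values > upper else values > upper
  if (all(out)) {
    warning("Tukey fences would remove every value; original set retained",
            call. = FALSE)
    out <- rep(FALSE, length(values))
  }
  list(surviving = values[!out], removed = values[out],
       fences = c(lower = lower, upper = upper))
}

#' Select the representative value per substance and unit track
#'
#' For each substance and each unit track with at least one value: screen
#' outliers with [tukey_fences()], then take the minimum of the survivors.
#'
#' @param studies Data.frame with columns `substance_id` and one or both of
#'   `value_mg_m3`, `value_ppm` (or a single `value` column with a `track`
#'   column).
#' @param tracks Which unit-track columns to collapse (named character
#'   vector `column -> track label`).
#' @inheritParams tukey_fences
#' @return Data.frame with `substance_id`, `unit_track`, `value`,
#'   `n_studies`, `n_outliers_removed`.
#' @examples
#' df <- data.frame(substance_id = "A", value_mg_m3 = c(10, 10, 10, 10, 1000))
#' select_representative(df) # value 10, one outlier removed
#' @export
select_representative <- function(studies,
                                  tracks = c(value_mg_m3 = "mg_m3",
                                             value_ppm = "ppm"),
                                  quartile = c("linear", "nearest"),
                                  tails = c("both", "high"), k = 1.5) {
  quartile <- match.arg(quartile)
  tails <- match.arg(tails)
  stopifnot(is.data.frame(studies), "substance_id" %in% names(studies))
  tracks <- tracks[names(tracks) %in% names(studies)]
  if (!length(tracks)) stop("no unit-track columns found", call. = FALSE)
  rows <- list()
  for (col in names(tracks)) {
    vals <- studies[[col]]
    keep <- !is.na(vals)
    sp <- split(vals[keep], studies$substance_id[keep])
    for (sid in names(sp)) {
      v <- sp[[sid]]
      fen <- tukey_fences(v, quartile = quartile, tails = tails, k = k)
      rows[[length(rows) + 1L]] <- data.frame(
        substance_id = sid,
        unit_track = unname(tracks[col]),
        value = min(fen$surviving),
        n_studies = length(v),
        n_outliers_removed = length(fen$removed),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "quartile_method") <- quartile
  attr(out, "tails") <- tails
  out
}
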