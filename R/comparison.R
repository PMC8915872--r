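# Cross-dataset verification: re-derive TTC values from supplementary
# inhalation datasets (local NOAEC mg/m3 + systemic NOAEL mg/kg-day, or
# local/systemic/general NOEC ppm), plus overlap, log-scale correlation and
# Welch t-test comparisons between datasets.

#' Re-derive TTC values per structural class from an external dataset
#'
#' Rows with a value of exactly 0 are dropped with a note (ambiguous
#' entries, as in supplementary-dataset footnotes); classes with fewer than
#' two remaining values are reported with the percentile suppressed.
#'
#' @param values Numeric endpoint values in mg/m3.
#' @param cramer_class Character class labels of the same length.
#' @param constants A [derivation_constants()] object.
#' @param p Percentile level (default 5).
#' @param method Percentile method (see [empirical_percentile()]).
#' @return Data.frame per class: `group`, `n_chemicals`, `n_dropped_zero`,
#'   `p5_mg_m3`, `ttc_mg_m3`, `noel_ug_kg_d`, `ttc_ug_person_d` (numeric
#'   columns `NA` where suppressed).
#' @export
rederive_ttc <- function(values, cramer_class,
                         constants = derivation_constants(), p = 5,
                         method = "linear") {
  stopifnot(length(values) == length(cramer_class))
  keep <- !is.na(values)
  values <- values[keep]; cramer_class <- cramer_class[keep]
  zero <- values == 0
  if (any(zero)) {
    message(sum(zero), " zero-valued record(s) dropped before percentile")
  }
  sp <- split(values[!zero], cramer_class[!zero])
  nz <- table(cramer_class[zero])
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    n0 <- if (g %in% names(nz)) as.integer(nz[[g]]) else 0L
    if (length(v) < 2L) {
      return(data.frame(group = g, n_chemicals = length(v),
                        n_dropped_zero = n0, p5_mg_m3 = NA_real_,
                        ttc_mg_m3 = NA_real_, noel_ug_kg_d = NA_real_,
                        ttc_ug_person_d = NA_real_, stringsAsFactors = FALSE))
    }
    p5 <- empirical_percentile(v, p, method)$value
    noel <- body_dose_noel(p5, constants)
    data.frame(group = g, n_chemicals = length(v), n_dropped_zero = n0,
               p5_mg_m3 = p5,
               ttc_mg_m3 = ttc_air_concentration(p5, constants),
               noel_ug_kg_d = noel,
               ttc_ug_person_d = ttc_person_day(noel, constants),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a systemic body-dose NOAEL to an equivalent air concentration
#'
#' Default conversion is the inverse of [body_dose_noel()] solved for
#' concentration: `C (mg/m3) = dose (mg/kg-d) x bw / (dexp x Vresp)`. The
#' source publications do not print their conversion, so the formula is a
#' configurable hook.
#'
#' @param noael_mg_kg_d Systemic NOAEL values in mg/kg-day (>= 0).
#' @param constants A [derivation_constants()] object.
#' @param conversion Optional replacement function
#'   `(noael_mg_kg_d, constants) -> mg/m3`.
#' @return Air concentrations in mg/m3.
#' @examples
#' carthew_systemic_to_air(1) # 60 / (0.17857 * 20) = 16.8
#' @export
carthew_systemic_to_air <- function(noael_mg_kg_d,
                                    constants = derivation_constants(),
                                    conversion = NULL) {
  constants <- .check_constants(constants)
  .check_nonneg(noael_mg_kg_d, "noael_mg_kg_d")
  if (!is.null(conversion)) return(conversion(noael_mg_kg_d, constants))
  noael_mg_kg_d * constants$bw / (constants$dexp * constants$vresp)
}

#' Convert ppm values to mg/m3 via the molar-volume relation
#'
#' `mg/m3 = ppm x MW / molar_volume`; values without a molecular weight
#' stay `NA` (a ppm-only comparison track).
#'
#' @param ppm Numeric ppm values.
#' @param mw Molecular weights, g/mol (`NA` allowed).
#' @param molar_volume Molar gas volume, L/mol.
#' @return mg/m3 values (`NA` where MW missing).
#' @export
ppm_to_mg_m3 <- function(ppm, mw, molar_volume = 24.45) {
  ppm * mw / molar_volume
}

#' Identifier overlap between two datasets
#'
#' Exact-match set algebra on a resolved common identifier namespace.
#' Duplicate identifiers within a dataset are deduplicated with a warning.
#'
#' @param ids_a,ids_b Character identifier vectors.
#' @return List with `intersection`, `a_only`, `b_only` and `counts`.
#' @export
overlap_by_id <- function(ids_a, ids_b) {
  if (anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    warning("duplicate identifiers within a dataset; deduplicated",
            call. = FALSE)
  }
  a <- unique(ids_a); b <- unique(ids_b)
  res <- list(intersection = intersect(a, b),
              a_only = setdiff(a, b),
              b_only = setdiff(b, a))
  res$counts <- c(n_a = length(a), n_b = length(b),
                  n_intersection = length(res$intersection),
                  n_a_only = length(res$a_only),
                  n_b_only = length(res$b_only))
  res
}

#' Pearson correlation of paired values on the log10 scale
#'
#' Pairs with a non-positive value on either side are excluded (and
#' counted in the `n_excluded` field).
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r`, `n_used`, `n_excluded`.
#' @export
log_pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3L) stop("need at least 3 positive pairs", call. = FALSE)
  list(r = stats::cor(log10(x[ok]), log10(y[ok])),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Two-sample t-test on log10 values
#'
#' Welch (unequal variance) by default; pooled-variance by flag. Inputs
#' are log10-transformed first (non-positive values excluded).
#'
#' @param x,y Numeric samples (positive values used), each n >= 2.
#' @param pooled Use the pooled-variance variant instead of Welch.
#' @return List with `t`, `p_value`, `df`, `variant`.
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  x <- log10(x[is.finite(x) & x > 0])
  y <- log10(y[is.finite(y) & y > 0])
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 in both samples",
                                             call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p_value = 1, df = NA_real_,
                  variant = if (pooled) "pooled" else "welch"))
    }
    stop("zero variance in both samples; t undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       variant = if (pooled) "pooled" else "welch")
}

#' Read a supplementary dataset in the local/systemic NOAEC dialect
#'
#' Expects columns for substance name, Cramer class, a local NOAEC in
#' mg/m3 and a systemic NOAEL in mg/kg-day; the column mapping is
#' configurable.
#'
#' @param path TSV file path.
#' @param col_map Named list mapping `name`, `cramer`, `local_mg_m3`,
#'   `systemic_mg_kg_d` to the file's column names.
#' @return Data.frame with canonical columns `name`, `cramer_class`,
#'   `local_noaec_mg_m3`, `systemic_noael_mg_kg_d`.
#' @export
read_carthew <- function(path,
                         col_map = list(name = "Name",
                                        cramer = "Cramer class",
                                        local_mg_m3 = "Local NOAEC (mg/m^3)",
                                        systemic_mg_kg_d = "Systemic NOAEL (mg/kg/day)")) {
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(unlist(col_map), names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data.frame(name = df[[col_map$name]],
             cramer_class = as.character(df[[col_map$cramer]]),
             local_noaec_mg_m3 = as.numeric(df[[col_map$local_mg_m3]]),
             systemic_noael_mg_kg_d = as.numeric(df[[col_map$systemic_mg_kg_d]]),
             stringsAsFactors = FALSE)
}

#' Read a supplementary dataset in the local/systemic/general NOEC ppm
#' dialect
#'
#' The general NOEC is the lower of the local and systemic values; when the
#' file supplies a general column it is validated against (and missing
#' entries filled by) that rule.
#'
#' @param path TSV file path.
#' @param col_map Named list mapping `casrn`, `cramer`, `local_ppm`,
#'   `systemic_ppm`, `general_ppm` to the file's column names.
#' @return Data.frame with canonical columns `casrn`, `cramer_class`,
#'   `local_noec_ppm`, `systemic_noec_ppm`, `general_noec_ppm`.
#' @export
read_escher <- function(path,
                        col_map = list(casrn = "CAS",
                                       cramer = "Cramer class",
                                       local_ppm = "Local_NOEC_ppm",
                                       systemic_ppm = "Systemic_NOEC_ppm",
                                       general_ppm = "General_NOEC_ppm")) {
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- unlist(col_map[c("casrn", "cramer", "local_ppm", "systemic_ppm")])
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  out <- data.frame(casrn = as.character(df[[col_map$casrn]]),
                    cramer_class = as.character(df[[col_map$cramer]]),
                    local_noec_ppm = as.numeric(df[[col_map$local_ppm]]),
                    systemic_noec_ppm = as.numeric(df[[col_map$systemic_ppm]]),
                    stringsAsFactors = FALSE)
  gen <- pmin(out$local_noec_ppm, out$systemic_noec_ppm, na.rm = TRUE)
  if (col_map$general_ppm %in% names(df)) {
    g <- as.numeric(df[[col_map$general_ppm]])
    g[is.na(g)] <- gen[is.na(g)]
    out$general_noec_ppm <- g
  } else {
    out$general_noec_ppm <- gen
  }
  out
}
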