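# Synthetic study-record generator with known ground truth, shaped like a
# processed multi-source toxicity-value extract: per-substance molecular
# weight, Cramer class and MOA profiler outcomes; per-substance study
# records with lognormal NO(A)EC values, mixed units, free-text study
# types, day/week/month durations, species name variants, injected
# ambiguous values and injected extreme outliers. Hidden truth goes to a
# sidecar table, never the pipeline-facing one.

#' Synthetic dataset configuration
#'
#' Defaults describe a plausible inhalation point-of-departure extract:
#' category log10(mg/m3) means chosen so that with sd = 1.0 the analytic
#' 5% quantile of the generating lognormal sits near published
#' representative-value percentiles (Cramer I ~0.058 mg/m3, Cramer III
#' ~0.030 mg/m3); about six studies per substance (1 + geometric, mean 6,
#' truncated at 30); a mixed unit vocabulary; 5% extreme outliers at
#' x10^4; 2% ambiguous (0 / -999) records; 10% per-profiler MOA
#' disagreement; 5% non-rodent species.
#'
#' @param n_substances Number of substances (>= 0).
#' @param category_params Named list `label -> c(mean, sd)` of log10
#'   (mg/m3) lognormal parameters per category.
#' @param category_weights Sampling weights over categories (default
#'   uniform).
#' @param moa_labels True-MOA label universe for the profilers.
#' @param studies_per_substance List with `mean` (of the geometric part +
#'   1) and `max`.
#' @param unit_mix Named probability weights over
#'   `ppm, mg/m3, mg/L, g/m3, ug/m3`.
#' @param outlier_rate Fraction of studies replaced by extreme values.
#' @param outlier_multiplier Log10 factor applied to outlier values.
#' @param ambiguous_rate Fraction of records set to 0 or -999.
#' @param profiler_disagreement_rate Probability each profiler deviates
#'   from the substance's true MOA.
#' @param nonrodent_rate Fraction of studies on non-rodent species.
#' @param mw_range Molecular weight range, g/mol.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   tables.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_substances = 400,
                         category_params = list(
                           "Cramer I" = c(mean = 0.41, sd = 1.0),
                           "Cramer III" = c(mean = 0.12, sd = 1.0)),
                         category_weights = NULL,
                         moa_labels = c("baseline", "reactive", "ester",
                                        "narcotic_amine"),
                         studies_per_substance = list(mean = 6, max = 30),
                         unit_mix = c("ppm" = 0.35, "mg/m3" = 0.35,
                                      "mg/L" = 0.1, "g/m3" = 0.1,
                                      "ug/m3" = 0.1),
                         outlier_rate = 0.05,
                         outlier_multiplier = 4,
                         ambiguous_rate = 0.02,
                         profiler_disagreement_rate = 0.1,
                         nonrodent_rate = 0.05,
                         mw_range = c(30, 400),
                         seed = 1L) {
  cfg <- list(n_substances = n_substances, category_params = category_params,
              category_weights = category_weights, moa_labels = moa_labels,
              studies_per_substance = studies_per_substance,
              unit_mix = unit_mix, outlier_rate = outlier_rate,
              outlier_multiplier = outlier_multiplier,
              ambiguous_rate = ambiguous_rate,
              profiler_disagreement_rate = profiler_disagreement_rate,
              nonrodent_rate = nonrodent_rate, mw_range = mw_range,
              seed = as.integer(seed))
  .validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

.validate_synth_config <- function(cfg) {
  err <- function(field, msg) {
    stop("invalid synth_config field '", field, "': ", msg, call. = FALSE)
  }
  if (!is.numeric(cfg$n_substances) || cfg$n_substances < 0 ||
      cfg$n_substances != round(cfg$n_substances)) {
    err("n_substances", "must be a non-negative integer")
  }
  for (rate in c("outlier_rate", "ambiguous_rate",
                 "profiler_disagreement_rate", "nonrodent_rate")) {
    v <- cfg[[rate]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      err(rate, "must be in [0, 1]")
    }
  }
  if (!length(cfg$category_params)) err("category_params", "must be non-empty")
  for (lab in names(cfg$category_params)) {
    pr <- cfg$category_params[[lab]]
    if (length(pr) < 2L || !is.finite(pr[2]) || pr[2] <= 0) {
      err("category_params", paste0("sd for '", lab, "' must be > 0"))
    }
  }
  if (any(cfg$unit_mix < 0) || sum(cfg$unit_mix) <= 0) {
    err("unit_mix", "weights must be non-negative with positive sum")
  }
  if (length(cfg$mw_range) != 2L || cfg$mw_range[1] <= 0 ||
      cfg$mw_range[2] < cfg$mw_range[1]) {
    err("mw_range", "must be (min, max) with 0 < min <= max")
  }
  if (cfg$studies_per_substance$mean < 1) {
    err("studies_per_substance", "mean must be >= 1")
  }
  invisible(cfg)
}

#' Analytic 5% quantile of a generating category
#'
#' On the log10 scale the category distribution is Normal(mean, sd), so
#' the analytic p-quantile of the mg/m3 values is
#' `10^(mean + z_p * sd)`.
#'
#' @param config A [synth_config()].
#' @param p Quantile level in (0, 1), default 0.05.
#' @return Named numeric vector of analytic quantiles (mg/m3) per
#'   category.
#' @export
synth_analytic_quantile <- function(config, p = 0.05) {
  z <- stats::qnorm(p)
  vapply(config$category_params,
         function(pr) 10^(pr[[1]] + z * pr[[2]]), numeric(1))
}

#' Generate synthetic substances
#'
#' Each substance gets an identifier, a molecular weight uniform in
#' `mw_range`, a category drawn from `category_params` (per
#' `category_weights`), a true MOA, and three profiler outcomes equal to
#' the true MOA with probability `1 - profiler_disagreement_rate` each,
#' otherwise a random other label.
#'
#' @param config A [synth_config()].
#' @return Data.frame with `substance_id`, `name`, `casrn`, `mw`,
#'   `cramer_class` (category label), `true_moa`, `verhaar_toxtree`,
#'   `verhaar_toolbox`, `oasis_moa`.
#' @export
generate_substances <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_substances
  if (n == 0L) {
    return(data.frame(substance_id = character(0), name = character(0),
                      casrn = character(0), mw = numeric(0),
                      cramer_class = character(0), true_moa = character(0),
                      verhaar_toxtree = character(0),
                      verhaar_toolbox = character(0),
                      oasis_moa = character(0), stringsAsFactors = FALSE))
  }
  set.seed(config$seed)
  cats <- names(config$category_params)
  w <- config$category_weights
  if (is.null(w)) w <- rep(1, length(cats))
  category <- sample(cats, n, replace = TRUE, prob = w)
  mw <- stats::runif(n, config$mw_range[1], config$mw_range[2])
  true_moa <- sample(config$moa_labels, n, replace = TRUE)
  flip <- function(truth) {
    dev <- stats::runif(n) < config$profiler_disagreement_rate
    out <- truth
    if (any(dev) && length(config$moa_labels) > 1L) {
      out[dev] <- vapply(truth[dev], function(t) {
        sample(setdiff(config$moa_labels, t), 1L)
      }, character(1))
    }
    out
  }
  data.frame(
    substance_id = sprintf("SYN%05d", seq_len(n)),
    name = sprintf("synthetic-chemical-%05d", seq_len(n)),
    casrn = sprintf("%05d-%02d-%d", seq_len(n), seq_len(n) %% 100,
                    seq_len(n) %% 10),
    mw = mw,
    cramer_class = category,
    true_moa = true_moa,
    verhaar_toxtree = flip(true_moa),
    verhaar_toolbox = flip(true_moa),
    oasis_moa = flip(true_moa),
    stringsAsFactors = FALSE
  )
}

.species_pool <- function() {
  list(rodent = c("Rat", "rat", "Rats", "Sprague-Dawley rat", "Wistar rat",
                  "Mouse", "mice", "B6C3F1 mouse", "Rabbit", "rabbits",
                  "New Zealand white rabbit"),
       other = c("dog", "Beagle dog", "monkey", "guinea pig", "human"))
}

.study_type_pool <- function() {
  c("subacute", "subchronic toxicity", "chronic", "repeat dose",
    "short-term repeat dose", "reproduction/developmental screening",
    "developmental toxicity", "multigeneration reproductive")
}

#' Generate synthetic study records for a set of substances
#'
#' For each substance, k studies (k = 1 + geometric with the configured
#' mean, truncated at `max`) with true NO(A)EC drawn lognormal from the
#' substance's category parameters (in mg/m3), then expressed in a unit
#' drawn from `unit_mix`. ppm values are back-converted through the molar
#' volume with the substance's MW so the round trip recovers the hidden
#' mg/m3 truth exactly. Outlier studies multiply the truth by
#' `10^outlier_multiplier`; ambiguous studies get a reported value of 0 or
#' -999. Durations are emitted across day/week/month spellings; species
#' are drawn from rodent name variants plus occasional non-rodents.
#'
#' @param substances Output of [generate_substances()], non-empty.
#' @param config A [synth_config()].
#' @return List of two data.frames: `records` (pipeline-facing: record_id,
#'   substance_id, name, study_type, study_duration_value,
#'   study_duration_units, exposure_route, toxval_type, toxval_numeric,
#'   toxval_units, species, source) and `truth` (sidecar: record_id,
#'   substance_id, true_category, true_moa, true_mg_m3, is_outlier,
#'   is_ambiguous).
#' @export
generate_studies <- function(substances, config) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(substances))
  if (nrow(substances) == 0L) stop("substances must be non-empty", call. = FALSE)
  set.seed(config$seed + 1L)
  sp <- config$studies_per_substance
  # mean of 1 + Geom(p) is 1/p, so p = 1/mean
  geo_p <- min(1 / sp$mean, 1)
  k <- pmin(1L + stats::rgeom(nrow(substances), prob = geo_p), sp$max)
  if (!is.null(sp$fixed)) k <- rep(as.integer(sp$fixed), nrow(substances))
  idx <- rep(seq_len(nrow(substances)), k)
  n <- length(idx)
  cat_mean <- vapply(substances$cramer_class[idx],
                     function(cl) config$category_params[[cl]][[1]],
                     numeric(1))
  cat_sd <- vapply(substances$cramer_class[idx],
                   function(cl) config$category_params[[cl]][[2]],
                   numeric(1))
  true_mg <- 10^stats::rnorm(n, cat_mean, cat_sd)

  is_outlier <- stats::runif(n) < config$outlier_rate
  value_mg <- true_mg * ifelse(is_outlier, 10^config$outlier_multiplier, 1)

  units <- sample(names(config$unit_mix), n, replace = TRUE,
                  prob = config$unit_mix)
  mw <- substances$mw[idx]
  # a substance lacking MW never gets an inconvertible ppm row
  units[units == "ppm" & is.na(mw)] <- "mg/m3"
  reported <- value_mg
  reported[units == "ppm"] <- value_mg[units == "ppm"] * 24.45 /
    mw[units == "ppm"]
  reported[units == "g/m3"] <- value_mg[units == "g/m3"] / 1000
  reported[units == "ug/m3"] <- value_mg[units == "ug/m3"] * 1000
  unit_label <- units
  unit_label[units == "mg/m3"] <-
    sample(c("mg/m3", "mg/m^3"), sum(units == "mg/m3"), replace = TRUE)

  is_ambiguous <- stats::runif(n) < config$ambiguous_rate
  reported[is_ambiguous] <- sample(c(0, -999), sum(is_ambiguous),
                                   replace = TRUE)

  dur_units <- sample(c("days", "day", "weeks", "wk", "months", "mo"),
                      n, replace = TRUE)
  dur_days <- stats::runif(n, 5, 400)
  fac <- duration_unit_factors()
  dur_value <- round(dur_days / unname(fac[dur_units]), 1)

  pool <- .species_pool()
  nonrodent <- stats::runif(n) < config$nonrodent_rate
  species <- character(n)
  species[!nonrodent] <- sample(pool$rodent, sum(!nonrodent), replace = TRUE)
  species[nonrodent] <- sample(pool$other, sum(nonrodent), replace = TRUE)

  records <- data.frame(
    record_id = sprintf("R%06d", seq_len(n)),
    substance_id = substances$substance_id[idx],
    name = substances$name[idx],
    study_type = sample(.study_type_pool(), n, replace = TRUE),
    study_duration_value = dur_value,
    study_duration_units = dur_units,
    exposure_route = sample(c("inhalation", "inhalation (whole body)"),
                            n, replace = TRUE),
    toxval_type = sample(c("NOAEC", "NOAEL", "NOEC", "NOEL"),
                         n, replace = TRUE),
    toxval_numeric = reported,
    toxval_units = unit_label,
    species = species,
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    record_id = records$record_id,
    substance_id = records$substance_id,
    true_category = substances$cramer_class[idx],
    true_moa = substances$true_moa[idx],
    true_mg_m3 = value_mg,
    is_outlier = is_outlier,
    is_ambiguous = is_ambiguous,
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Generate and write a full synthetic dataset to disk
#'
#' Writes `substances.tsv`, `records.tsv` and the hidden-truth sidecar
#' `truth.tsv` as UTF-8 tab-separated tables with header rows.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of generated tables.
#' @export
write_synthetic_dataset <- function(config, out_dir) {
  subs <- generate_substances(config)
  st <- generate_studies(subs, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(subs, "substances.tsv")
  wr(st$records, "records.tsv")
  wr(st$truth, "truth.tsv")
  invisible(list(substances = subs, records = st$records, truth = st$truth))
}
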