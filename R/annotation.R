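# Annotation and extraction of relevant inhalation study records:
# study-length classification, unit standardization (ppm and mg/m3 tracks),
# ambiguous-record removal, species normalization, duration adjustment and
# the four-criterion relevance filter.

#' Default study-type token lists
#'
#' Case-insensitive substring tokens used to classify free-text `study_type`
#' strings. `chronic` deliberately excludes matches that are really
#' "subchronic" (handled first).
#'
#' @return Named list of character vectors of lower-case tokens.
#' @export
study_type_tokens <- function() {
  list(
    multigenerational = c("multigen", "multi-gen"),
    developmental = c("develop"),
    reproductive = c("reproduct", "reproduction"),
    subchronic = c("subchronic", "sub-chronic"),
    chronic = c("chronic"),
    repeat_dose = c("repeat", "short-term", "short term")
  )
}

#' Default duration-unit conversion factors (to days)
#'
#' Weeks convert at 7 days; months at 30.44 days (mean Gregorian month).
#'
#' @return Named numeric vector mapping lower-case unit spellings to days.
#' @export
duration_unit_factors <- function() {
  c(day = 1, days = 1, d = 1,
    week = 7, weeks = 7, wk = 7, wks = 7,
    month = 30.44, months = 30.44, mo = 30.44, mos = 30.44)
}

#' Convert a study duration to days
#'
#' @param value Numeric duration values (may be `NA`).
#' @param units Character duration units (day/week/month spellings, may be
#'   `NA`).
#' @return Numeric vector of durations in days (`NA` where undecidable).
#' @export
duration_in_days <- function(value, units) {
  if (length(units) == 1L && length(value) > 1L) units <- rep(units, length(value))
  stopifnot(length(value) == length(units))
  if (any(value < 0, na.rm = TRUE)) {
    stop("negative study duration", call. = FALSE)
  }
  fac <- duration_unit_factors()
  u <- tolower(trimws(as.character(units)))
  f <- unname(fac[u])
  out <- value * f
  out[is.na(value) | is.na(f)] <- NA_real_
  out
}

.match_tokens <- function(study_type, tokens) {
  st <- tolower(as.character(study_type))
  st[is.na(st)] <- ""
  has <- function(tok) {
    m <- rep(FALSE, length(st))
    for (t in tok) m <- m | grepl(t, st, fixed = TRUE)
    m
  }
  lapply(tokens, has)
}

#' Classify study length from study type and duration
#'
#' Implements the annotation rules: reproductive, developmental and
#' multigenerational labels come only from the `study_type` text, never from
#' duration. A repeat-dose study is chronic if its type says chronic or its
#' duration exceeds 100 days (after week x7 / month x30.44 conversion);
#' subchronic if its type says so or the duration is >= 35 and < 100 days;
#' subacute if the duration is < 35 days. A study of exactly 100 days with
#' an uninformative type is left `"unclassified"` (the two stated duration
#' rules leave that single point uncovered), as is any record where neither
#' tokens nor duration decide.
#'
#' @param study_type Character vector of free-text study types.
#' @param duration_value Numeric durations (may be `NA`).
#' @param duration_units Character duration units (may be `NA`).
#' @param tokens Token configuration, see [study_type_tokens()].
#' @return Character vector with levels subacute, subchronic, chronic,
#'   reproductive, developmental, multigenerational, unclassified.
#' @examples
#' classify_study_length("repeat dose", 120, "days")  # chronic
#' classify_study_length("repeat dose", 4, "weeks")   # subacute (28 d)
#' classify_study_length("reproduction", 20, "days")  # reproductive
#' @export
classify_study_length <- function(study_type, duration_value = NA_real_,
                                  duration_units = NA_character_,
                                  tokens = study_type_tokens()) {
  n <- max(length(study_type), length(duration_value), length(duration_units))
  study_type <- rep_len(study_type, n)
  duration_value <- rep_len(duration_value, n)
  duration_units <- rep_len(duration_units, n)
  days <- duration_in_days(duration_value, duration_units)
  tk <- .match_tokens(study_type, tokens)

  out <- rep("unclassified", n)
  # duration rules (lowest precedence)
  out[!is.na(days) & days < 35] <- "subacute"
  out[!is.na(days) & days >= 35 & days < 100] <- "subchronic"
  out[!is.na(days) & days > 100] <- "chronic"
  # type tokens override duration; subchronic token checked before chronic
  # so "subchronic" never matches the chronic tier
  out[tk$chronic & !tk$subchronic] <- "chronic"
  out[tk$subchronic] <- "subchronic"
  out[tk$reproductive] <- "reproductive"
  out[tk$developmental] <- "developmental"
  out[tk$multigenerational] <- "multigenerational"
  out
}

#' Recognized exposure-concentration unit spellings
#' @return Named character vector mapping lower-case spellings to canonical
#'   units (`ppm`, `mg/m3`, `mg/L`, `g/m3`, `ug/m3`).
#' @export
unit_vocabulary <- function() {
  c("ppm" = "ppm",
    "mg/m3" = "mg/m3", "mg/m^3" = "mg/m3", "mg/m³" = "mg/m3",
    "mg/l" = "mg/L",
    "g/m3" = "g/m3", "g/m^3" = "g/m3", "g/m³" = "g/m3",
    "ug/m3" = "ug/m3", "ug/m^3" = "ug/m3", "µg/m3" = "ug/m3",
    "µg/m^3" = "ug/m3", "µg/m³" = "ug/m3", "ug/m³" = "ug/m3")
}

#' Standardize exposure concentrations onto parallel mg/m3 and ppm tracks
#'
#' mg/m3 track: g/m3 x 1000, ug/m3 / 1000, mg/L taken as equivalent,
#' ppm x MW / 24.45 (only when the molecular weight is known). ppm track:
#' the mg/m3-family value x 24.45 / MW (only when MW is known), ppm values
#' unchanged. A missing MW leaves the inconvertible track `NA` — never
#' guessed. Unrecognized units yield `NA` on both tracks and are flagged in
#' the `recognized` column so callers can route them to a rejects report.
#'
#' @param value Numeric concentration values.
#' @param unit Character unit strings.
#' @param mw Molecular weights in g/mol (`NA` when unknown).
#' @param molar_volume Molar gas volume, L/mol (default 24.45).
#' @return A data.frame with `value_mg_m3`, `value_ppm` and `recognized`.
#' @examples
#' standardize_units(10, "ppm", mw = 48.90) # 20 mg/m3, 10 ppm
#' standardize_units(2, "g/m3", mw = NA)    # 2000 mg/m3
#' @export
standardize_units <- function(value, unit, mw = NA_real_,
                              molar_volume = 24.45) {
  n <- max(length(value), length(unit), length(mw))
  value <- rep_len(as.numeric(value), n)
  unit <- rep_len(as.character(unit), n)
  mw <- rep_len(as.numeric(mw), n)
  if (any(!is.finite(value))) stop("values must be finite", call. = FALSE)

  vocab <- unit_vocabulary()
  canon <- unname(vocab[tolower(trimws(unit))])
  recognized <- !is.na(canon)

  mg <- rep(NA_real_, n)
  ppm <- rep(NA_real_, n)

  mg[recognized & canon == "mg/m3"] <- value[recognized & canon == "mg/m3"]
  mg[recognized & canon == "mg/L"] <- value[recognized & canon == "mg/L"]
  i <- recognized & canon == "g/m3";  mg[i] <- value[i] * 1000
  i <- recognized & canon == "ug/m3"; mg[i] <- value[i] / 1000
  i <- recognized & canon == "ppm"
  ppm[i] <- value[i]
  j <- i & !is.na(mw)
  mg[j] <- value[j] * mw[j] / molar_volume
  # back-fill the ppm track from the mg/m3 family where MW is known
  k <- recognized & canon != "ppm" & !is.na(mw)
  ppm[k] <- mg[k] * molar_volume / mw[k]

  data.frame(value_mg_m3 = mg, value_ppm = ppm, recognized = recognized)
}

#' Remove ambiguous toxicity values (0 or -999)
#'
#' @param records A data.frame with a `toxval_numeric` column.
#' @return The data.frame without rows whose value is exactly 0 or -999;
#'   the removal count is attached as `attr(, "n_removed")`. An empty
#'   result raises a warning.
#' @export
remove_ambiguous <- function(records) {
  stopifnot(is.data.frame(records), "toxval_numeric" %in% names(records))
  bad <- records$toxval_numeric %in% c(0, -999)
  out <- records[!bad, , drop = FALSE]
  if (nrow(out) == 0L && nrow(records) > 0L) {
    warning("all ", sum(bad), " records were ambiguous (0 or -999); ",
            "result is empty", call. = FALSE)
  }
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Map free-text species names to a rodent/other tag
#'
#' Rats, mice and rabbits (including partial strain names such as
#' "Sprague-Dawley rat") map to `"rodent"`; everything else to `"other"`.
#'
#' @param species Character vector of free-text species names.
#' @return Character vector of `"rodent"` / `"other"`.
#' @export
normalize_species <- function(species) {
  s <- tolower(as.character(species))
  s[is.na(s)] <- ""
  pat <- "\\brats?\\b|\\bmouse\\b|\\bmice\\b|\\brabbits?\\b|murine"
  ifelse(grepl(pat, s), "rodent", "other")
}

#' Adjust toxicity values for exposure duration
#'
#' Multiplies a value by a per-study-length factor. The shipped default
#' table is all 1.0: the derivation carries duration-adjusted columns but no
#' adjustment factors are asserted, so the defaults deliberately do nothing;
#' factors are configuration.
#'
#' @param value Numeric values.
#' @param study_length Character study-length labels.
#' @param factors Named numeric vector/list of factors per label; labels
#'   missing from `factors` raise a configuration error.
#' @return Adjusted numeric values.
#' @examples
#' adjust_for_duration(10, "subchronic", c(subchronic = 0.5)) # 5
#' @export
adjust_for_duration <- function(value, study_length,
                                factors = default_duration_factors()) {
  n <- max(length(value), length(study_length))
  value <- rep_len(value, n)
  study_length <- rep_len(study_length, n)
  factors <- unlist(factors)
  miss <- setdiff(unique(study_length), names(factors))
  if (length(miss)) {
    stop("no duration-adjustment factor configured for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  value * unname(factors[study_length])
}

#' Default duration-adjustment factor table (identity)
#' @return Named numeric vector, all 1.0.
#' @export
default_duration_factors <- function() {
  c(subacute = 1, subchronic = 1, chronic = 1, reproductive = 1,
    developmental = 1, multigenerational = 1, unclassified = 1)
}

#' NO(A)EL / NO(A)EC point-of-departure type whitelist
#' @param toxval_type Character vector of free-text POD types.
#' @return Logical vector: TRUE where the type is a no-observed-effect
#'   level/concentration variant (NOEL, NOEC, NOAEL, NOAEC).
#' @export
is_noael_type <- function(toxval_type) {
  grepl("^\\s*no\\(?a?\\)?e[lc]\\s*$", tolower(as.character(toxval_type)))
}

#' Annotate raw study records
#'
#' Joins substance molecular weights, converts durations to days, classifies
#' study length, normalizes species and standardizes units onto the parallel
#' mg/m3 and ppm tracks (plus duration-adjusted copies).
#'
#' @param records Data.frame of raw study rows (`substance_id`, `study_type`,
#'   `study_duration_value`, `study_duration_units`, `exposure_route`,
#'   `toxval_type`, `toxval_numeric`, `toxval_units`, `species`).
#' @param substances Data.frame with `substance_id` and `mw`.
#' @param duration_factors See [adjust_for_duration()].
#' @param tokens See [study_type_tokens()].
#' @param molar_volume Molar gas volume, L/mol.
#' @return A new data.frame (inputs are never mutated) with added columns
#'   `duration_days`, `study_length`, `species_group`, `value_mg_m3`,
#'   `value_ppm`, `value_mg_m3_adjusted`, `value_ppm_adjusted`,
#'   `unit_recognized`.
#' @export
annotate_studies <- function(records, substances,
                             duration_factors = default_duration_factors(),
                             tokens = study_type_tokens(),
                             molar_volume = 24.45) {
  stopifnot(is.data.frame(records), is.data.frame(substances))
  mw <- substances$mw[match(records$substance_id, substances$substance_id)]
  out <- records
  out$duration_days <- duration_in_days(records$study_duration_value,
                                        records$study_duration_units)
  out$study_length <- classify_study_length(records$study_type,
                                            records$study_duration_value,
                                            records$study_duration_units,
                                            tokens = tokens)
  out$species_group <- normalize_species(records$species)
  u <- standardize_units(records$toxval_numeric, records$toxval_units,
                         mw = mw, molar_volume = molar_volume)
  out$value_mg_m3 <- u$value_mg_m3
  out$value_ppm <- u$value_ppm
  out$unit_recognized <- u$recognized
  out$value_mg_m3_adjusted <- adjust_for_duration(u$value_mg_m3,
                                                  out$study_length,
                                                  duration_factors)
  out$value_ppm_adjusted <- adjust_for_duration(u$value_ppm,
                                                out$study_length,
                                                duration_factors)
  out
}

#' Filter annotated studies down to the relevant inhalation records
#'
#' Keeps rows satisfying all four criteria: (a) study length among
#' subacute/subchronic/chronic/reproductive/developmental/multigenerational
#' (a repeat-dose record whose duration cannot be classified is kept and
#' counted separately); (b) inhalation exposure route; (c) a NO(A)EL /
#' NO(A)EC point-of-departure type; (d) rodent species. Per-criterion
#' attrition counts are attached as `attr(, "attrition")`. The criteria are
#' evaluated as independent masks, so the result is order-independent.
#'
#' @param records An annotated data.frame from [annotate_studies()].
#' @param tokens See [study_type_tokens()] (used for the repeat-dose carve
#'   out).
#' @return Filtered data.frame with an `attrition` attribute.
#' @export
filter_relevant <- function(records, tokens = study_type_tokens()) {
  stopifnot(is.data.frame(records))
  lengths_ok <- records$study_length %in%
    c("subacute", "subchronic", "chronic", "reproductive",
      "developmental", "multigenerational")
  repeat_unclassified <- records$study_length == "unclassified" &
    .match_tokens(records$study_type, tokens)$repeat_dose
  a <- lengths_ok | repeat_unclassified
  b <- grepl("inhal", tolower(as.character(records$exposure_route)))
  c_ <- is_noael_type(records$toxval_type)
  d <- records$species_group == "rodent"
  keep <- a & b & c_ & d
  out <- records[keep, , drop = FALSE]
  attr(out, "attrition") <- c(
    n_in = nrow(records),
    fail_study_length = sum(!a),
    kept_repeat_unclassified = sum(repeat_unclassified & keep),
    fail_route = sum(!b),
    fail_toxval_type = sum(!c_),
    fail_species = sum(!d),
    n_kept = sum(keep)
  )
  out
}
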