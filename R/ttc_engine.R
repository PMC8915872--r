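# TTC derivation formulas and the tiered Kroes decision tree.

#' Derivation constants for inhalation TTC formulas
#'
#' Bundles the fixed constants used throughout the derivation chain:
#' the exposure-duration adjustment `dexp` (intermittent 6 h/day, 5 d/week
#' study exposure converted to a continuous-equivalent), the total
#' uncertainty factor (25, conventionally decomposed as 10 x 2.5), the
#' default human respiratory volume (20 m3/day, consumer scenario), the
#' default human body weight (60 kg) and the molar volume of an ideal gas
#' at 25 C / 1 atm (24.45 L/mol) used for ppm <-> mg/m3 conversion.
#'
#' @param dexp Dimensionless exposure-duration adjustment. Default
#'   `(6/24) * (5/7)`.
#' @param uf_total Total uncertainty factor applied to the 5th-percentile
#'   point of departure. Default 25 (= 10 x 2.5).
#' @param vresp Human respiratory volume, m3/day. Default 20.
#' @param bw Human body weight, kg. Default 60.
#' @param molar_volume Molar gas volume, L/mol. Default 24.45.
#' @return An object of class `ttc_constants` (a validated named list).
#' @examples
#' k <- derivation_constants()
#' k$dexp # 0.1785714...
#' @export
derivation_constants <- function(dexp = (6 / 24) * (5 / 7),
                                 uf_total = 25,
                                 vresp = 20,
                                 bw = 60,
                                 molar_volume = 24.45) {
  out <- list(dexp = dexp, uf_total = uf_total, vresp = vresp,
              bw = bw, molar_volume = molar_volume)
  for (nm in names(out)) {
    v <- out[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("constant '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(out, class = "ttc_constants")
}

.check_constants <- function(constants) {
  if (!inherits(constants, "ttc_constants")) {
    constants <- do.call(derivation_constants, as.list(constants))
  }
  constants
}

.check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and >= 0", call. = FALSE)
  }
  invisible(x)
}

#' Air-concentration TTC from a 5th-percentile NO(A)EC
#'
#' `TTC (mg/m3) = P5 (mg/m3) x dexp / uf_total`.
#'
#' @param p5_mg_m3 5th-percentile NO(A)EC in mg/m3 (vectorized, >= 0).
#' @param constants A [derivation_constants()] object.
#' @return TTC in mg/m3.
#' @examples
#' ttc_air_concentration(0.0579) # ~ 0.000414
#' @export
ttc_air_concentration <- function(p5_mg_m3, constants = derivation_constants()) {
  constants <- .check_constants(constants)
  .check_nonneg(p5_mg_m3, "p5_mg_m3")
  p5_mg_m3 * constants$dexp / constants$uf_total
}

#' Body-dose NOEL from a 5th-percentile NO(A)EC
#'
#' `NOEL (ug/kg/d) = P5 (mg/m3) x dexp x (Vresp / bw) x 1000`.
#'
#' @inheritParams ttc_air_concentration
#' @return NOEL in ug/kg-day.
#' @examples
#' body_dose_noel(0.0579) # ~ 3.446
#' @export
body_dose_noel <- function(p5_mg_m3, constants = derivation_constants()) {
  constants <- .check_constants(constants)
  .check_nonneg(p5_mg_m3, "p5_mg_m3")
  p5_mg_m3 * constants$dexp * (constants$vresp / constants$bw) * 1000
}

#' Per-person daily TTC from a body-dose NOEL
#'
#' `TTC (ug/person/d) = NOEL (ug/kg/d) x bw / uf_total`. This is the unique
#' formula consistent with the paired air-concentration columns: composing it
#' with [body_dose_noel()] equals [ttc_air_concentration()] x Vresp x 1000
#' for every input.
#'
#' @param noel_ug_kg_d Body-dose NOEL in ug/kg-day (vectorized, >= 0).
#' @inheritParams ttc_air_concentration
#' @return TTC in ug/person-day.
#' @export
ttc_person_day <- function(noel_ug_kg_d, constants = derivation_constants()) {
  constants <- .check_constants(constants)
  .check_nonneg(noel_ug_kg_d, "noel_ug_kg_d")
  noel_ug_kg_d * constants$bw / constants$uf_total
}

#' Convert an air-concentration TTC to a per-person daily TTC
#'
#' `TTC (ug/person/d) = TTC (mg/m3) x Vresp x 1000`.
#'
#' @param ttc_mg_m3 Air-concentration TTC in mg/m3 (vectorized, >= 0).
#' @inheritParams ttc_air_concentration
#' @return TTC in ug/person-day.
#' @examples
#' air_conc_to_person_day(8.5e-3) # 170
#' @export
air_conc_to_person_day <- function(ttc_mg_m3, constants = derivation_constants()) {
  constants <- .check_constants(constants)
  .check_nonneg(ttc_mg_m3, "ttc_mg_m3")
  ttc_mg_m3 * constants$vresp * 1000
}

#' Full derivation chain for one or more groups
#'
#' Applies the three derivation formulas to per-group 5th percentiles and
#' returns a table in the layout of a TTC results table (group, n, 5th
#' percentile, TTC mg/m3, NOEL ug/kg-d, TTC ug/person-d). Groups whose
#' chemical count falls below `min_n` are kept but tagged
#' `insufficient_n = TRUE` (too few substances to carry a headline TTC).
#'
#' @param group Character vector of group labels.
#' @param n_chemicals Integer vector of chemical counts per group.
#' @param p5_mg_m3 Numeric vector of 5th percentiles in mg/m3.
#' @param constants A [derivation_constants()] object.
#' @param min_n Minimum group size for a headline TTC (default 20).
#' @return A data.frame with one row per group.
#' @export
derive_ttc_table <- function(group, n_chemicals, p5_mg_m3,
                             constants = derivation_constants(),
                             min_n = 20) {
  constants <- .check_constants(constants)
  stopifnot(length(group) == length(n_chemicals),
            length(group) == length(p5_mg_m3))
  noel <- body_dose_noel(p5_mg_m3, constants)
  data.frame(
    group = as.character(group),
    n_chemicals = as.integer(n_chemicals),
    p5_mg_m3 = p5_mg_m3,
    ttc_mg_m3 = ttc_air_concentration(p5_mg_m3, constants),
    noel_ug_kg_d = noel,
    ttc_ug_person_d = ttc_person_day(noel, constants),
    insufficient_n = n_chemicals < min_n,
    stringsAsFactors = FALSE
  )
}

#' Oral TTC thresholds used by the tiered Kroes decision tree
#'
#' @return Named numeric vector of ug/day thresholds.
#' @export
kroes_thresholds <- function() {
  c(genotoxic_alert = 0.15,
    op_carbamate = 18,
    cramer_III = 90,
    cramer_II = 540,
    cramer_I = 1800)
}

#' Tiered Kroes decision-tree assignment
#'
#' Walks the tiered decision tree for a single substance: exclusion classes
#' (inorganics, polymers, bioaccumulative substances, proteins) and the
#' cohort of concern (five high-potency carcinogen classes, steroids
#' included) are excluded from the TTC approach entirely; a genotoxicity
#' structural alert outside the cohort receives the most conservative value
#' (0.15 ug/day); organophosphates and carbamates receive 18 ug/day;
#' otherwise the Cramer class thresholds apply (III 90, II 540, I
#' 1800 ug/day). A substance with no flags and no Cramer class is
#' "not assigned" (never an error).
#'
#' @param flags A list (or [kroes_flags()] object) with logical fields
#'   `excluded_class`, `cohort_of_concern`, `genotox_alert`,
#'   `organophosphate`, `carbamate`, `steroid` and a `cramer_class` field in
#'   `c("I", "II", "III", "none")`.
#' @return A list with `category` (character) and `ttc_ug_day` (numeric,
#'   `NA` for excluded / not assigned).
#' @examples
#' kroes_assign(kroes_flags(genotox_alert = TRUE))$ttc_ug_day # 0.15
#' kroes_assign(kroes_flags(cramer_class = "I"))$ttc_ug_day   # 1800
#' @export
kroes_assign <- function(flags) {
  flags <- unclass(flags)
  flags <- do.call(kroes_flags, flags[!vapply(flags, is.null, logical(1))])
  thr <- kroes_thresholds()
  if (flags$excluded_class) {
    return(list(category = "excluded", ttc_ug_day = NA_real_))
  }
  # steroids are one of the cohort-of-concern classes
  if (flags$cohort_of_concern || flags$steroid) {
    return(list(category = "excluded", ttc_ug_day = NA_real_))
  }
  if (flags$genotox_alert) {
    return(list(category = "genotoxic alert", ttc_ug_day = unname(thr["genotoxic_alert"])))
  }
  if (flags$organophosphate || flags$carbamate) {
    return(list(category = "OP/carbamate", ttc_ug_day = unname(thr["op_carbamate"])))
  }
  switch(flags$cramer_class,
    "III" = list(category = "Cramer III", ttc_ug_day = unname(thr["cramer_III"])),
    "II"  = list(category = "Cramer II",  ttc_ug_day = unname(thr["cramer_II"])),
    "I"   = list(category = "Cramer I",   ttc_ug_day = unname(thr["cramer_I"])),
    list(category = "not assigned", ttc_ug_day = NA_real_)
  )
}

#' Construct a validated set of Kroes decision-tree flags
#'
#' @param excluded_class,cohort_of_concern,genotox_alert,organophosphate,carbamate,steroid
#'   Logical scalars, default `FALSE`.
#' @param cramer_class One of `"I"`, `"II"`, `"III"`, `"none"`.
#' @return A list of class `kroes_flags`.
#' @export
kroes_flags <- function(excluded_class = FALSE, cohort_of_concern = FALSE,
                        genotox_alert = FALSE, organophosphate = FALSE,
                        carbamate = FALSE, steroid = FALSE,
                        cramer_class = "none") {
  lg <- list(excluded_class = excluded_class,
             cohort_of_concern = cohort_of_concern,
             genotox_alert = genotox_alert,
             organophosphate = organophosphate,
             carbamate = carbamate,
             steroid = steroid)
  for (nm in names(lg)) {
    if (!is.logical(lg[[nm]]) || length(lg[[nm]]) != 1L || is.na(lg[[nm]])) {
      stop("flag '", nm, "' must be TRUE or FALSE", call. = FALSE)
    }
  }
  cramer_class <- match.arg(cramer_class, c("I", "II", "III", "none"))
  structure(c(lg, list(cramer_class = cramer_class)), class = "kroes_flags")
}
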