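# Aquatic mode-of-action consensus: harmonize up to three profiler outcomes
# (Toxtree Verhaar, Toolbox Verhaar, OASIS acute MOA) into one consensus
# label, with inter-scheme agreement statistics.

#' Canonical aquatic mode-of-action labels
#' @return Character vector of canonical labels.
#' @export
canonical_moa_labels <- function() {
  c("unclassified", "baseline", "ester", "less_inert", "narcotic_amine",
    "phenol_aniline", "aldehyde", "ab_unsat_alcohol", "specifically_acting",
    "reactive")
}

#' Default conservativeness ordering over canonical MOA labels
#'
#' Low to high concern: unclassified < baseline < ester < less_inert <
#' narcotic_amine < phenol_aniline < aldehyde < ab_unsat_alcohol <
#' specifically_acting < reactive. "unclassified" sits below baseline for
#' consensus tie-breaking only; substances whose consensus is unclassified
#' are not carried into TTC groups. The ordering between the intermediate
#' classes is a declared configuration default, not a fact of the
#' underlying profilers.
#'
#' @return Named integer vector (rank, higher = more conservative).
#' @export
moa_conservativeness_default <- function() {
  lv <- canonical_moa_labels()
  stats::setNames(seq_along(lv), lv)
}

#' Default raw-label -> canonical mapping tables per profiling scheme
#'
#' Verhaar schemes map class 1 -> baseline, 2 -> less_inert, 3 -> reactive,
#' 4 -> specifically_acting, 5 / unclassifiable -> unclassified. The OASIS
#' acute MOA table maps its named categories onto the same canonical set.
#' Matching is by case-insensitive substring.
#'
#' @return Named list (scheme -> named character vector pattern ->
#'   canonical label).
#' @export
moa_mapping_default <- function() {
  verhaar <- c("class 1" = "baseline",
               "class 2" = "less_inert",
               "class 3" = "reactive",
               "class 4" = "specifically_acting",
               "class 5" = "unclassified",
               "not possible to classify" = "unclassified",
               "unclassified" = "unclassified")
  oasis <- c("basesurface narcotic" = "baseline",
             "base surface narcotic" = "baseline",
             "baseline" = "baseline",
             "narcotic amine" = "narcotic_amine",
             "ester" = "ester",
             "phenol" = "phenol_aniline",
             "aniline" = "phenol_aniline",
             "aldehyde" = "aldehyde",
             "unsaturated alcohol" = "ab_unsat_alcohol",
             "reactive" = "reactive",
             "specific" = "specifically_acting",
             "no alert" = "unclassified",
             "unclassified" = "unclassified")
  list(verhaar_toxtree = verhaar, verhaar_toolbox = verhaar,
       oasis_moa = oasis)
}

#' Map a raw profiler label to its canonical MOA label
#'
#' Table-driven, case-insensitive substring match. Unknown raw labels map
#' to `"unclassified"` with a warning, never an error.
#'
#' @param scheme One of `"verhaar_toxtree"`, `"verhaar_toolbox"`,
#'   `"oasis_moa"` (or any scheme present in `mapping`).
#' @param raw_label Character vector of raw profiler outputs.
#' @param mapping Mapping configuration, see [moa_mapping_default()].
#' @return Character vector of canonical labels.
#' @examples
#' map_outcome("verhaar_toxtree", "Class 1 (narcosis or baseline toxicity)")
#' @export
map_outcome <- function(scheme, raw_label, mapping = moa_mapping_default()) {
  if (!scheme %in% names(mapping)) {
    stop("unknown scheme '", scheme, "'", call. = FALSE)
  }
  tab <- mapping[[scheme]]
  raw <- tolower(as.character(raw_label))
  out <- rep(NA_character_, length(raw))
  for (pat in names(tab)) {
    hit <- is.na(out) & grepl(pat, raw, fixed = TRUE)
    out[hit] <- tab[[pat]]
  }
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sum(unknown), " raw label(s) not in the ", scheme,
            " mapping table; mapped to 'unclassified'", call. = FALSE)
    out[unknown] <- "unclassified"
  }
  out
}

#' Consensus of up to three canonical MOA labels
#'
#' Unanimity of the present labels wins; otherwise a strict majority wins;
#' otherwise (all distinct, or two disagreeing labels) the most
#' conservative label under `ordering` is taken. The result is invariant
#' under permutation of the inputs.
#'
#' @param labels Character vector of 1-3 canonical labels (`NA` entries
#'   are treated as missing and dropped).
#' @param ordering Conservativeness ranks, see
#'   [moa_conservativeness_default()].
#' @return List with `consensus` and `rule_used`
#'   (`"unanimity"`/`"majority"`/`"conservative"`).
#' @examples
#' moa_consensus(c("baseline", "reactive", "reactive")) # majority: reactive
#' @export
moa_consensus <- function(labels, ordering = moa_conservativeness_default()) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("at least one MOA label required",
                                 call. = FALSE)
  bad <- setdiff(labels, names(ordering))
  if (length(bad)) {
    stop("labels not in the conservativeness ordering: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) == 1L) {
    return(list(consensus = names(tab), rule_used = "unanimity"))
  }
  if (max(tab) > length(labels) / 2) {
    return(list(consensus = names(tab)[which.max(tab)],
                rule_used = "majority"))
  }
  list(consensus = names(which.max(ordering[unique(labels)])),
       rule_used = "conservative")
}

#' Consensus MOA per substance from a table of profiler outcomes
#'
#' @param outcomes Data.frame with `substance_id` and canonical-label
#'   columns (default `verhaar_toxtree`, `verhaar_toolbox`, `oasis_moa`).
#' @param schemes Names of the label columns to combine.
#' @param ordering See [moa_consensus()].
#' @return Data.frame with `substance_id`, the input labels, `consensus`,
#'   `rule_used`.
#' @export
consensus_table <- function(outcomes,
                            schemes = c("verhaar_toxtree", "verhaar_toolbox",
                                        "oasis_moa"),
                            ordering = moa_conservativeness_default()) {
  stopifnot(is.data.frame(outcomes), "substance_id" %in% names(outcomes))
  schemes <- intersect(schemes, names(outcomes))
  if (!length(schemes)) stop("no scheme columns found", call. = FALSE)
  res <- lapply(seq_len(nrow(outcomes)), function(i) {
    moa_consensus(unlist(outcomes[i, schemes], use.names = FALSE), ordering)
  })
  out <- outcomes[, c("substance_id", schemes), drop = FALSE]
  out$consensus <- vapply(res, `[[`, character(1), "consensus")
  out$rule_used <- vapply(res, `[[`, character(1), "rule_used")
  out
}

#' Confusion matrix between two labeling schemes
#'
#' Rows are scheme A's labels ("predictions"), columns scheme B's
#' ("reference"); this orientation is recorded in the `"orientation"`
#' attribute of the result. Substances with a missing label in either
#' scheme are excluded and counted in the `"n_unpaired"` attribute.
#'
#' @param labels_a,labels_b Character vectors of canonical labels over the
#'   same substances.
#' @param levels Label universe (default the canonical labels present).
#' @return Integer matrix with row/column names; attributes `orientation`
#'   and `n_unpaired`.
#' @export
confusion_matrix <- function(labels_a, labels_b, levels = NULL) {
  stopifnot(length(labels_a) == length(labels_b))
  ok <- !is.na(labels_a) & !is.na(labels_b)
  if (is.null(levels)) levels <- sort(unique(c(labels_a[ok], labels_b[ok])))
  m <- table(factor(labels_a[ok], levels = levels),
             factor(labels_b[ok], levels = levels))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("scheme_a", "scheme_b")
  attr(m, "orientation") <-
    "rows = scheme A (prediction), columns = scheme B (reference)"
  attr(m, "n_unpaired") <- sum(!ok)
  m
}

#' Precision and recall for one label of a confusion matrix
#'
#' With the [confusion_matrix()] orientation (rows = scheme A =
#' prediction, columns = scheme B = reference): precision is the fraction
#' of A's `target_label` calls that B also labels so (diagonal / row
#' total); recall is the fraction of B's `target_label` substances that A
#' recovers (diagonal / column total). An empty row or column yields `NA`
#' (undefined), never 0.
#'
#' @param m Matrix from [confusion_matrix()].
#' @param target_label Label to score.
#' @return List with `precision` and `recall` in \[0, 1\] (or `NA`).
#' @export
precision_recall <- function(m, target_label) {
  if (!target_label %in% rownames(m)) {
    stop("label '", target_label, "' not in matrix", call. = FALSE)
  }
  diag_ct <- m[target_label, target_label]
  rs <- sum(m[target_label, ])
  cs <- sum(m[, target_label])
  list(precision = if (rs > 0) diag_ct / rs else NA_real_,
       recall = if (cs > 0) diag_ct / cs else NA_real_)
}
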