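# End-to-end pipeline: raw study records -> annotated/filtered inhalation
# records -> per-substance representative values -> per-group 5th
# percentiles -> TTC table.

#' Run the full inhalation TTC derivation pipeline
#'
#' Chains the stages: ambiguous-record removal, annotation (study length,
#' species, unit tracks), the four-criterion relevance filter, Tukey-fence
#' outlier screening with per-substance minimum representative values on
#' the mg/m3 track, per-group empirical (optionally bootstrapped) 5th
#' percentiles, and the TTC derivation formulas.
#'
#' @param records Raw study records (see [annotate_studies()]).
#' @param substances Substance table with `substance_id`, `mw` and the
#'   grouping column.
#' @param group_col Column of `substances` defining the TTC groups
#'   (default `"cramer_class"`).
#' @param constants A [derivation_constants()] object.
#' @param bootstrap Use the bootstrapped-median 5th percentile instead of
#'   the plain empirical one.
#' @param n_replicates Bootstrap replicates (default 10000).
#' @param seed Root seed for the bootstrap.
#' @param min_n Minimum group size for a headline TTC.
#' @param p Percentile level (default 5).
#' @return A list with `ttc` (the derivation table, one row per group),
#'   `representative`, `annotated`, `attrition` and `group_stats`.
#' @export
run_ttc_pipeline <- function(records, substances, group_col = "cramer_class",
                             constants = derivation_constants(),
                             bootstrap = FALSE, n_replicates = 10000,
                             seed = 1, min_n = 20, p = 5) {
  stopifnot(group_col %in% names(substances))
  clean <- remove_ambiguous(records)
  ann <- annotate_studies(clean, substances)
  filt <- filter_relevant(ann)
  rep_vals <- select_representative(filt)
  mg <- rep_vals[rep_vals$unit_track == "mg_m3", , drop = FALSE]
  grp <- substances[[group_col]][match(mg$substance_id,
                                       substances$substance_id)]
  stats_tab <- group_distribution_summary(mg$value, grp, p = p,
                                          bootstrap = bootstrap,
                                          n_replicates = n_replicates,
                                          seed = seed)
  p5 <- if (bootstrap) {
    ifelse(is.na(stats_tab$boot_median), stats_tab$p5, stats_tab$boot_median)
  } else stats_tab$p5
  ttc <- derive_ttc_table(stats_tab$group, stats_tab$n, p5,
                          constants = constants, min_n = min_n)
  list(ttc = ttc, representative = rep_vals, annotated = filt,
       attrition = c(n_ambiguous_removed = attr(clean, "n_removed"),
                     attr(filt, "attrition")),
       group_stats = stats_tab)
}

#' Write a data.frame as a UTF-8 tab-separated table
#' @param df Data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a UTF-8 tab-separated table
#' @param path Input file.
#' @return Data.frame (column names preserved verbatim).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}
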