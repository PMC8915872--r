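# Study-length classification, unit standardization, ambiguous-record
# removal, species normalization, duration adjustment and the relevance
# filter.

test_that("study length follows the token and duration rules", {
  cases <- list(
    list("repeat dose", 120, "days", "chronic"),       # > 100 d
    list("repeat dose", 100, "days", "unclassified"),  # exactly 100 d uncovered
    list("repeat dose", 99, "days", "subchronic"),
    list("repeat dose", 35, "days", "subchronic"),     # lower boundary inclusive
    list("repeat dose", 34, "days", "subacute"),
    list("repeat dose", 4, "weeks", "subacute"),       # 28 d < 35
    list("repeat dose", 15, "weeks", "chronic"),       # 105 d
    list("repeat dose", 4, "months", "chronic"),       # 121.8 d
    list("chronic study", 10, "days", "chronic"),      # token beats duration
    list("subchronic toxicity", 200, "days", "subchronic"),
    list("reproduction", 20, "days", "reproductive"),  # token only, never duration
    list("developmental screening", 300, "days", "developmental"),
    list("multigeneration study", NA, NA, "multigenerational"),
    list("repeat dose", NA, NA, "unclassified")
  )
  for (cs in cases) {
    expect_equal(classify_study_length(cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                 info = paste(cs[[1]], cs[[2]], cs[[3]]))
  }
  expect_error(classify_study_length("repeat dose", -5, "days"), "negative")
})

test_that("unit standardization follows the molar-volume relation and scalings", {
  r <- standardize_units(1.0, "ppm", mw = 24.45)
  expect_equal(r$value_mg_m3, 1.0)
  expect_equal(r$value_ppm, 1.0)
  r <- standardize_units(10, "ppm", mw = 48.90)
  expect_equal(r$value_mg_m3, 20.0)
  expect_equal(r$value_ppm, 10)
  expect_equal(standardize_units(2.0, "g/m3")$value_mg_m3, 2000)
  expect_equal(standardize_units(500, "ug/m3")$value_mg_m3, 0.5)
  expect_equal(standardize_units(3, "mg/L")$value_mg_m3, 3)

  # missing MW leaves the inconvertible track NA, never guessed
  r <- standardize_units(5, "ppm", mw = NA)
  expect_true(is.na(r$value_mg_m3))
  expect_equal(r$value_ppm, 5)
  r <- standardize_units(5, "mg/m3", mw = NA)
  expect_equal(r$value_mg_m3, 5)
  expect_true(is.na(r$value_ppm))

  # unrecognized units are flagged, not dropped silently
  r <- standardize_units(5, "furlongs", mw = 100)
  expect_false(r$recognized)
  expect_true(is.na(r$value_mg_m3) && is.na(r$value_ppm))
})

test_that("ppm <-> mg/m3 round trip is exact to >= 12 significant digits", {
  set.seed(11)
  mw <- runif(200, 20, 500)
  mg <- 10^runif(200, -4, 4)
  ppm <- standardize_units(mg, rep("mg/m3", 200), mw)$value_ppm
  back <- standardize_units(ppm, rep("ppm", 200), mw)$value_mg_m3
  expect_equal(back, mg, tolerance = 1e-12)
})

test_that("ambiguous records (0 / -999) are removed and counted", {
  df <- data.frame(toxval_numeric = c(1.2, 0, -999, 3))
  out <- remove_ambiguous(df)
  expect_equal(out$toxval_numeric, c(1.2, 3))
  expect_equal(attr(out, "n_removed"), 2L)

  clean <- data.frame(toxval_numeric = c(1, 2, 3))
  expect_equal(nrow(remove_ambiguous(clean)), 3L)

  expect_warning(out2 <- remove_ambiguous(data.frame(toxval_numeric = c(-999, -999))),
                 "ambiguous")
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "n_removed"), 2L)
})

test_that("remove_ambiguous removes exactly the injected ambiguous rows", {
  w <- make_synth(n = 150, seed = 21, ambiguous_rate = 0.08)
  out <- remove_ambiguous(w$records)
  expect_setequal(out$record_id, w$truth$record_id[!w$truth$is_ambiguous])
})

test_that("species normalization maps rodent name variants", {
  expect_equal(normalize_species(c("Rat", "dog", "Sprague-Dawley rat",
                                   "MICE", "New Zealand white rabbit",
                                   "guinea pig", NA)),
               c("rodent", "other", "rodent", "rodent", "rodent",
                 "other", "other"))
})

test_that("duration adjustment multiplies by configured factors", {
  expect_equal(adjust_for_duration(10, "chronic"), 10)  # defaults: identity
  expect_equal(adjust_for_duration(10, "subchronic", c(subchronic = 0.5)), 5)
  expect_equal(adjust_for_duration(0.2, "subacute", c(subacute = 0.25)), 0.05)
  expect_error(adjust_for_duration(1, "chronic", c(subacute = 1)),
               "chronic")
})

test_that("the relevance filter applies all four criteria", {
  subs <- data.frame(substance_id = c("A", "B"), mw = c(100, 50))
  rec <- data.frame(
    substance_id = c("A", "A", "A", "A", "B"),
    study_type = c("chronic", "chronic", "chronic", "repeat dose", "chronic"),
    study_duration_value = c(200, 200, 200, NA, 200),
    study_duration_units = "days",
    exposure_route = c("inhalation", "oral", "inhalation", "inhalation",
                       "inhalation"),
    toxval_type = c("NOAEC", "NOAEL", "LOAEL", "NOEL", "NOAEC"),
    toxval_numeric = c(1, 2, 3, 4, 5),
    toxval_units = "mg/m3",
    species = c("rat", "rat", "rat", "rat", "dog"),
    stringsAsFactors = FALSE
  )
  ann <- annotate_studies(rec, subs)
  out <- filter_relevant(ann)
  # kept: row 1 (all criteria) and row 4 (repeat dose, unclassifiable
  # duration, kept and counted separately)
  expect_equal(out$toxval_numeric, c(1, 4))
  at <- attr(out, "attrition")
  expect_equal(unname(at["n_in"]), 5)
  expect_equal(unname(at["n_kept"]), 2)
  expect_equal(unname(at["kept_repeat_unclassified"]), 1)
  expect_equal(unname(at["fail_route"]), 1)
  expect_equal(unname(at["fail_toxval_type"]), 1)
  expect_equal(unname(at["fail_species"]), 1)
})

test_that("filtering is order-independent and does not mutate its input", {
  w <- make_synth(n = 60, seed = 22)
  ann <- annotate_studies(w$records, w$substances)
  snapshot <- ann
  kept_ids <- filter_relevant(ann)$record_id
  expect_identical(ann, snapshot)  # no mutation

  # apply the four criteria sequentially in several permutations
  masks <- list(
    a = function(d) filter_relevant(d)$record_id, # combined reference
    route = function(d) d[grepl("inhal", tolower(d$exposure_route)), ],
    type = function(d) d[is_noael_type(d$toxval_type), ],
    species = function(d) d[d$species_group == "rodent", ]
  )
  length_mask <- function(d) {
    d[d$study_length %in% c("subacute", "subchronic", "chronic",
                            "reproductive", "developmental",
                            "multigenerational") |
        (d$study_length == "unclassified" &
           grepl("repeat|short", tolower(d$study_type))), ]
  }
  seq_filters <- list(masks$route, masks$type, masks$species, length_mask)
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    d <- ann
    for (i in perm) d <- seq_filters[[i]](d)
    expect_setequal(d$record_id, kept_ids)
  }
})

test_that("annotation fills parallel unit tracks consistent with MW", {
  w <- make_synth(n = 40, seed = 23, ambiguous_rate = 0)
  ann <- annotate_studies(w$records, w$substances)
  mw <- w$substances$mw[match(ann$substance_id, w$substances$substance_id)]
  both <- !is.na(ann$value_mg_m3) & !is.na(ann$value_ppm)
  expect_true(any(both))
  expect_equal(ann$value_mg_m3[both],
               ann$value_ppm[both] * mw[both] / 24.45, tolerance = 1e-12)
  # pipeline-facing mg/m3 equals hidden truth for non-ambiguous records
  expect_equal(ann$value_mg_m3, w$truth$true_mg_m3, tolerance = 1e-10)
})
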