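# Synthetic generator: determinism, configured rates, unit round trips,
# analytic quantile recovery.

test_that("config validation names the offending field", {
  expect_error(synth_config(outlier_rate = 1.5), "outlier_rate")
  expect_error(synth_config(n_substances = -1), "n_substances")
  expect_error(synth_config(category_params = list(a = c(0, -1))),
               "category_params")
  expect_error(synth_config(mw_range = c(10, 5)), "mw_range")
})

test_that("generation is deterministic under a fixed config and seed", {
  a <- make_synth(n = 40, seed = 123)
  b <- make_synth(n = 40, seed = 123)
  expect_identical(a$substances, b$substances)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c_ <- make_synth(n = 40, seed = 124)
  expect_false(identical(a$records, c_$records))
})

test_that("substance generation honours trivial configs", {
  empty <- generate_substances(synth_config(n_substances = 0))
  expect_equal(nrow(empty), 0L)
  agree <- generate_substances(synth_config(n_substances = 50,
                                            profiler_disagreement_rate = 0,
                                            seed = 5))
  expect_true(all(agree$verhaar_toxtree == agree$true_moa))
  expect_true(all(agree$verhaar_toolbox == agree$true_moa))
  expect_true(all(agree$oasis_moa == agree$true_moa))
  expect_true(all(agree$mw >= 30 & agree$mw <= 400))
})

test_that("profiler disagreement matches the closed-form expectation", {
  rate <- 0.1
  subs <- generate_substances(synth_config(n_substances = 1000,
                                           profiler_disagreement_rate = rate,
                                           seed = 9))
  any_disagree <- with(subs, verhaar_toxtree != true_moa |
                         verhaar_toolbox != true_moa |
                         oasis_moa != true_moa)
  expected <- 1 - (1 - rate)^3  # 0.271
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(mean(any_disagree) - expected), 4 * se)
})

test_that("study counts and injection rates behave as configured", {
  w <- make_synth(n = 30, seed = 2,
                  studies_per_substance = list(mean = 6, max = 30, fixed = 5))
  expect_true(all(table(w$records$substance_id) == 5L))

  clean <- make_synth(n = 80, seed = 3, ambiguous_rate = 0, outlier_rate = 0)
  expect_false(any(clean$records$toxval_numeric %in% c(0, -999)))
  expect_false(any(clean$truth$is_outlier))

  dirty <- make_synth(n = 200, seed = 4, ambiguous_rate = 0.1)
  amb <- dirty$records$toxval_numeric %in% c(0, -999)
  expect_identical(amb, dirty$truth$is_ambiguous)
})

test_that("ppm records round-trip to the hidden mg/m3 truth", {
  w <- make_synth(n = 150, seed = 6, ambiguous_rate = 0)
  ppm <- w$records$toxval_units == "ppm"
  expect_gt(sum(ppm), 20)
  mw <- w$substances$mw[match(w$records$substance_id,
                              w$substances$substance_id)]
  back <- w$records$toxval_numeric[ppm] * mw[ppm] / 24.45
  expect_equal(back, w$truth$true_mg_m3[ppm], tolerance = 1e-10)
})

test_that("a substance without MW never receives an inconvertible ppm row", {
  cfg <- synth_config(n_substances = 25, seed = 8,
                      unit_mix = c("ppm" = 1, "mg/m3" = 0, "mg/L" = 0,
                                   "g/m3" = 0, "ug/m3" = 0))
  subs <- generate_substances(cfg)
  subs$mw <- NA_real_
  st <- generate_studies(subs, cfg)
  expect_false(any(st$records$toxval_units == "ppm"))
})

test_that("empirical category quantiles converge to the analytic lognormal quantile", {
  # one category, log10 mean -1, sd 0.5, one study per substance
  cfg <- synth_config(
    n_substances = 500,
    category_params = list(only = c(mean = -1, sd = 0.5)),
    studies_per_substance = list(mean = 1, max = 1, fixed = 1),
    outlier_rate = 0, ambiguous_rate = 0, seed = 31)
  st <- generate_studies(generate_substances(cfg), cfg)
  analytic <- synth_analytic_quantile(cfg)[["only"]]
  expect_equal(log10(analytic), -1 + qnorm(0.05) * 0.5)
  p5 <- empirical_percentile(st$truth$true_mg_m3, 5)$value
  expect_lt(abs(log10(p5) - log10(analytic)) / abs(log10(analytic)), 0.10)

  cfg2 <- synth_config(
    n_substances = 2000,
    category_params = list(only = c(mean = -1, sd = 0.5)),
    studies_per_substance = list(mean = 1, max = 1, fixed = 1),
    outlier_rate = 0, ambiguous_rate = 0, seed = 32)
  st2 <- generate_studies(generate_substances(cfg2), cfg2)
  p5b <- empirical_percentile(st2$truth$true_mg_m3, 5)$value
  expect_lt(abs(log10(p5b) - log10(analytic)) / abs(log10(analytic)), 0.05)
})

test_that("written dataset round-trips through TSV with matching identifiers", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_substances = 15, seed = 12)
  tabs <- write_synthetic_dataset(cfg, dir)
  rec <- read_tsv(file.path(dir, "records.tsv"))
  tru <- read_tsv(file.path(dir, "truth.tsv"))
  expect_identical(rec$record_id, tru$record_id)
  expect_equal(nrow(rec), nrow(tabs$records))
  expect_setequal(read_tsv(file.path(dir, "substances.tsv"))$substance_id,
                  tabs$substances$substance_id)
})
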