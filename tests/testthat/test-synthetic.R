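base_cfg <- function(seed = 1, noise = list(mz_jitter_ppm = 0,
                                            intensity_cv = 0, baseline = 0)) {
  sim_config(
    seed = seed,
    formulas = list(list(
      formula = "C14H14O6",
      isomers = list(list(rt = 5.5, width = 0.3, height = 1e6)),
      ms2 = list("35" = ms2_channels(
        parent = 0.2,
        fg = list(list(n_co2 = 1, n_h2o = 0, n_ch4o = 0, fraction = 0.8)))))),
    noise = noise
  )
}

test_that("a fixed seed makes the generated run byte-identical", {
  cfg <- base_cfg(seed = 9, noise = list(mz_jitter_ppm = 3,
                                         intensity_cv = 0.2, baseline = 5))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(simulate_run(cfg), f1)
  write_fixture_csv(simulate_run(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("different seeds change the jitter but not the truth structure", {
  noisy <- list(mz_jitter_ppm = 3, intensity_cv = 0.2, baseline = 0)
  r1 <- simulate_run(base_cfg(seed = 1, noise = noisy))
  r2 <- simulate_run(base_cfg(seed = 2, noise = noisy))
  expect_false(identical(r1$ms2[[1]]$peaks$mz, r2$ms2[[1]]$peaks$mz))
  expect_identical(table(r1$truth$channel), table(r2$truth$channel))
})

test_that("noise-free channels reproduce the metrics exactly (closed loop)", {
  run <- simulate_run(base_cfg())
  # parent-only spectrum is a single peak at the deprotonated parent
  expect_length(run$ms2, 1)
  m <- compute_metrics_single(run$ms2[[1]], "C14H14O6")
  expect_equal(m$pct_parent, 20, tolerance = 1e-12)
  expect_equal(m$pct_fg, 80, tolerance = 1e-12)

  only_parent <- sim_config(seed = 4, formulas = list(list(
    formula = "C9H10O5",
    isomers = list(list(rt = 2, width = 0.2, height = 1e5)),
    ms2 = list("35" = ms2_channels(parent = 1)))))
  run2 <- simulate_run(only_parent)
  expect_equal(run2$ms2[[1]]$peaks$mz, mz_deprotonated("C9H10O5"))
  expect_equal(n_peaks(run2$ms2[[1]]$peaks), 1)
})

test_that("every emitted peak carries exactly one truth label", {
  cfg <- base_cfg(seed = 13, noise = list(mz_jitter_ppm = 2,
                                          intensity_cv = 0.3, baseline = 2))
  run <- simulate_run(cfg)
  n_emitted <- sum(vapply(run$ms1, function(s) n_peaks(s$peaks), numeric(1))) +
    sum(vapply(run$ms2, function(s) n_peaks(s$peaks), numeric(1)))
  expect_equal(nrow(run$truth), n_emitted)
  expect_false(any(duplicated(run$truth[, c("record", "mz")])))
})

test_that("channel fractions are validated", {
  expect_error(ms2_channels(parent = 0.8, radical = 0.3), "> 1")
  expect_error(ms2_channels(parent = -0.1), "non-negative")
  expect_error(sim_config(seed = 1.5), "integer")
})

test_that("halogen-channel peaks all carry mass defects >= 0.5", {
  cfg <- sim_config(seed = 6, formulas = list(list(
    formula = "C14H14O6",
    isomers = list(list(rt = 5, width = 0.3, height = 1e6)),
    ms2 = list("35" = ms2_channels(parent = 0.5, halogen = 0.5)))),
    noise = list(mz_jitter_ppm = 3, intensity_cv = 0.1, baseline = 0))
  run <- simulate_run(cfg)
  hal <- run$truth[run$truth$channel == "halogen", ]
  expect_gt(nrow(hal), 0)
  expect_true(all(hal$mz - floor(hal$mz) >= 0.5))
})

test_that("DOM mixtures reduce to the base run and shift with hydrophobicity", {
  cfg <- base_cfg(seed = 17)
  expect_identical(make_dom_mixture(cfg, 1, populations = NULL),
                   simulate_run(cfg))

  mixture_xic <- function(w_hydrophobic, seed) {
    cfg <- base_cfg(seed = seed)
    run <- make_dom_mixture(
      cfg, n_isomers_per_formula = 150,
      populations = list(
        list(weight = 1 - w_hydrophobic, rt_range = c(0.5, 3)),
        list(weight = w_hydrophobic, rt_range = c(4, 10))))
    extract_xic(run$ms1, mz_deprotonated("C14H14O6"), 5)
  }
  meds <- vapply(c(0.25, 0.5, 0.75), function(w) {
    ci_profile(mixture_xic(w, seed = 23))$percentiles[["50"]]
  }, numeric(1))
  # an even split puts the median between the two elution modes
  x50 <- mixture_xic(0.5, seed = 23)
  mode_lo <- x50$rt[x50$rt < 3.5][which.max(x50$intensity[x50$rt < 3.5])]
  mode_hi <- x50$rt[x50$rt > 3.5][which.max(x50$intensity[x50$rt > 3.5])]
  expect_gt(meds[2], mode_lo)
  expect_lt(meds[2], mode_hi)
  # more hydrophobic mass monotonically delays the median
  expect_true(all(diff(meds) > 0))
})

test_that("recovery experiments are exact without noise and track truth with it", {
  cfg <- base_cfg(seed = 100)
  r0 <- recovery_experiment(cfg, n_reps = 3, metric = "pct_fg")
  expect_equal(r0$sd, 0)
  expect_equal(r0$estimate, 80, tolerance = 1e-12)

  cfgn <- base_cfg(seed = 100, noise = list(mz_jitter_ppm = 2,
                                            intensity_cv = 0.2, baseline = 0))
  r1 <- recovery_experiment(cfgn, n_reps = 12, metric = "pct_fg")
  expect_gt(r1$sd, 0)
  expect_lt(abs(r1$estimate - 80), 3 * max(r1$sd, 1e-6))
  # doubling the intensity noise must not bias the ratio metric
  cfg2 <- base_cfg(seed = 100, noise = list(mz_jitter_ppm = 2,
                                            intensity_cv = 0.4, baseline = 0))
  r2 <- recovery_experiment(cfg2, n_reps = 12, metric = "pct_fg")
  expect_lt(abs(r2$estimate - 80), 3 * max(r2$sd, 1e-6))
  expect_error(recovery_experiment(cfg, n_reps = 1), ">= 2")
})
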