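test_that("noiseless fermentation metrics recover the generator truth exactly", {
  p <- fermentation_sim_params(noise_cv = 0, seed = 7)
  sim <- simulate_fermentation(p)
  m <- fermentation_metrics(sim$course, csp_window = sim$truth$csp_window)
  expect_equal(m$lipid_yield_g_per_g, p$true_lipid_yield)
  expect_equal(m$lipid_content, sim$truth$lipid_content_final)
  expect_equal(m$csp_g_per_g_per_day, sim$truth$csp)
  expect_equal(tail(m$lfdcw_gL, 1), sim$truth$lfdcw_final)
  expect_false(sim$clipped)
  # glucose starts at the stated batch concentration and is monotone
  expect_equal(sim$course$glucose_gL[1], 150)
  expect_true(all(diff(sim$course$glucose_gL) <= 0))
})

test_that("the generator is deterministic under a fixed seed", {
  p <- fermentation_sim_params(noise_cv = 0.05, seed = 11)
  a <- simulate_fermentation(p)
  b <- simulate_fermentation(p)
  expect_identical(a$course, b$course)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_time_course(a$course, f1)
  write_time_course(simulate_fermentation(p)$course, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and different seeds differ
  c2 <- simulate_fermentation(fermentation_sim_params(noise_cv = 0.05, seed = 12))
  expect_false(identical(a$course, c2$course))
})

test_that("yield recovery at 5% noise stays within 3 standard errors", {
  yields <- vapply(1:20, function(i) {
    sim <- simulate_fermentation(fermentation_sim_params(noise_cv = 0.05,
                                                         seed = 400 + i))
    fermentation_metrics(sim$course)$lipid_yield_g_per_g
  }, numeric(1))
  se <- stats::sd(yields) / sqrt(length(yields))
  expect_lt(abs(mean(yields) - 0.20), 3 * se)
})

test_that("generator parameter validation enforces carbon closure", {
  expect_error(fermentation_sim_params(true_lipid_yield = 0.6,
                                       true_biomass_yield = 0.5),
               "carbon closure")
  expect_error(fermentation_sim_params(noise_cv = 0.6), "noise_cv")
  expect_error(fermentation_sim_params(lipogenesis_onset_day = 7), "onset")
  expect_error(fermentation_sim_params(sampling_days = c(0, 1, 3, 5)),
               "onset day")
})

test_that("assay traces invert to the true specific activity", {
  p <- assay_sim_params(true_specific_activity = 1.4, noise_sd = 0, seed = 3)
  sim <- simulate_assay_plate(p)
  est <- vapply(sim$traces, function(k) pta_specific_activity(k)$value,
                numeric(1))
  expect_equal(est, rep(1.4, p$n_replicates))
  # zero activity, zero background: flat traces, estimate 0
  p0 <- assay_sim_params(true_specific_activity = 0, noise_sd = 0, seed = 3)
  tr <- simulate_assay_plate(p0)$traces
  expect_true(all(vapply(tr, function(k) diff(range(k$absorbance)), numeric(1)) == 0))
  expect_equal(pta_specific_activity(tr[[1]])$value, 0)
})

test_that("assay estimates at plausible read noise are within 5% of truth", {
  p <- assay_sim_params(true_specific_activity = 1, noise_sd = 0.005,
                        n_replicates = 4, times_min = 0:10, seed = 21)
  sim <- simulate_assay_plate(p)
  est <- vapply(sim$traces, function(k) pta_specific_activity(k)$value,
                numeric(1))
  expect_lt(abs(mean(est) - 1) / 1, 0.05)
  # determinism
  sim2 <- simulate_assay_plate(p)
  expect_identical(lapply(sim$traces, `[[`, "absorbance"),
                   lapply(sim2$traces, `[[`, "absorbance"))
})
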