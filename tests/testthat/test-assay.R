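test_that("DTNB specific activity follows Beer-Lambert arithmetic", {
  # slope 0.135 A/min, eps 13.5, path 1 cm, 1 mL reaction, 10 uL at 1 mg/mL
  k <- absorbance_kinetics(0:5, 0.135 * (0:5))
  out <- pta_specific_activity(k)
  expect_equal(out$value, 1.0)
  expect_equal(out$slope, 0.135)
  expect_equal(out$r_squared, 1.0)
  # flat trace: zero activity with a flag, not an error
  flat <- pta_specific_activity(absorbance_kinetics(0:5, rep(0.1, 6)))
  expect_equal(flat$value, 0)
  expect_equal(flat$flag, "nonpositive_slope")
  # linear in slope, inverse-linear in protein load
  k2 <- absorbance_kinetics(0:5, 0.270 * (0:5))
  expect_equal(pta_specific_activity(k2)$value, 2.0)
  k3 <- absorbance_kinetics(0:5, 0.135 * (0:5), protein_mg_per_ml = 2)
  expect_equal(pta_specific_activity(k3)$value, 0.5)
})

test_that("saturated readings are dropped before the fit", {
  t <- 0:10
  a <- 0.3 * t          # exceeds 2.0 AU from t = 7
  out <- pta_specific_activity(absorbance_kinetics(t, a))
  expect_true(out$truncated)
  expect_equal(out$n_used, sum(a <= 2))
  expect_equal(out$slope, 0.3)
  expect_error(absorbance_kinetics(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(absorbance_kinetics(0, 1), "at least two")
})

test_that("phosphoketolase readout normalizes to protein (and time)", {
  expect_equal(xpk_normalized_absorbance(0.6, 0.5), 1.2)
  expect_equal(xpk_normalized_absorbance(0, 0.5), 0)
  out <- xpk_normalized_absorbance(0.6, 0.5, reaction_time_min = 30)
  expect_equal(attr(out, "per_min"), 1.2 / 30)
  expect_error(xpk_normalized_absorbance(0.6, 0), "positive")
})

test_that("fold change divides by the parent mean only", {
  expect_equal(fold_change(2, c(2, 2, 2)), 1.0)
  expect_equal(fold_change(3.0, c(1.5, 1.5)), 2.0)
  expect_equal(fold_change(2, c(1, 3)), 1.0)
  expect_equal(fold_change(c(1, 2, 4), c(2, 2)), c(0.5, 1, 2))
  expect_error(fold_change(1, c(0, 0)), "positive")
  expect_error(fold_change(1, c(-2, 1)), "positive")
})

test_that("Bodipy fluorescence normalizes to OD600", {
  expect_equal(bodipy_fl_od(5000, 10), 500)
  expect_equal(bodipy_fl_od(0, 10), 0)
  expect_equal(bodipy_fl_od(2 * 5000, 2 * 10), 500)
  expect_error(bodipy_fl_od(100, 0), "positive")
})

test_that("fermentation metrics compute yield, content, LFDCW and CSP", {
  tc <- fermentation_time_course(
    time_d = 0:5,
    glucose_gL = c(150, 140, 110, 75, 40, 10),
    dcw_gL = c(4, 20, 40, 45, 50, 55),
    lipid_gL = c(2, 3, 10, 15, 20, 25))
  m <- fermentation_metrics(tc)
  expect_equal(m$lipid_yield_g_per_g, (25 - 2) / (150 - 10))
  expect_equal(m$lipid_content, 25 / 55)
  expect_equal(m$lfdcw_gL, tc$dcw_gL - tc$lipid_gL)
  # constant LFDCW of 30 over days 2-5, lipid 10 -> 25: CSP = 15 / (30 x 3)
  expect_equal(m$lfdcw_gL[3:6], rep(30, 4))
  expect_equal(m$csp_g_per_g_per_day, 15 / (30 * 3))
  expect_equal(fermentation_metrics(tc, csp_mean = "endpoint")$csp_g_per_g_per_day,
               15 / (30 * 3))
  # whole-batch arithmetic from the simple worked example
  tc2 <- fermentation_time_course(c(0, 2, 5), c(150, 100, 10),
                                  c(5, 20, 58), c(0, 10, 30))
  expect_equal(fermentation_metrics(tc2)$lipid_yield_g_per_g, 30 / 140)
  # zero lipid change in the window gives CSP 0
  tc3 <- fermentation_time_course(c(0, 2, 5), c(150, 100, 10),
                                  c(5, 40, 40), c(0, 10, 10))
  expect_equal(fermentation_metrics(tc3)$csp_g_per_g_per_day, 0)
})

test_that("metrics are invariant under concentration unit scaling", {
  tc <- fermentation_time_course(0:5, c(150, 140, 110, 75, 40, 10),
                                 c(4, 20, 40, 45, 50, 55),
                                 c(2, 3, 10, 15, 20, 25))
  s <- 0.1
  tcs <- fermentation_time_course(0:5, s * tc$glucose_gL, s * tc$dcw_gL,
                                  s * tc$lipid_gL)
  a <- fermentation_metrics(tc); b <- fermentation_metrics(tcs)
  expect_equal(a$lipid_yield_g_per_g, b$lipid_yield_g_per_g)
  expect_equal(a$lipid_content, b$lipid_content)
  expect_equal(a$csp_g_per_g_per_day, b$csp_g_per_g_per_day)
})

test_that("time-course invariants are enforced", {
  expect_error(fermentation_time_course(0:2, c(100, 120, 90), c(5, 5, 5),
                                        c(1, 1, 1)),
               "non-increasing")
  expect_error(fermentation_time_course(0:2, c(100, 90, 80), c(5, 5, 2),
                                        c(1, 1, 3)),
               "below lipid")
  expect_error(fermentation_time_course(0:1, c(100, 90), c(5, 5), c(1, 1, 1)),
               "equal length")
  tc <- fermentation_time_course(c(0, 2, 5), c(100, 100, 100), c(5, 6, 7),
                                 c(0, 1, 2))
  expect_error(fermentation_metrics(tc), "no glucose consumed")
  tc2 <- fermentation_time_course(c(0, 1, 4), c(100, 90, 50), c(5, 6, 7),
                                  c(0, 1, 2))
  expect_error(fermentation_metrics(tc2, csp_window = c(2, 5)), "sampling days")
})

test_that("time-course TSV round trip preserves the data", {
  tc <- fermentation_time_course(0:5, c(150, 140, 110, 75, 40, 10),
                                 c(4, 20, 40, 45, 50, 55),
                                 c(2, 3, 10, 15, 20, 25),
                                 extra = data.frame(citrate_gL = rep(0.5, 6)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_time_course(tc, p)
  back <- read_time_course(p)
  expect_equal(as.data.frame(back), as.data.frame(tc))
  writeLines("time_d\tglucose_gL\n0\t100", p)
  expect_error(read_time_course(p), "missing column")
})
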