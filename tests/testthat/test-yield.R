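test_that("native pathway needs exactly 18 glucose per triolein", {
  sol <- min_substrate(yield_problem(native_network()))
  expect_equal(sol$status, "optimal")
  expect_equal(as.character(sol$substrate_per_product), "18")
  expect_equal(round(sol$mass_yield_g_per_g, 2), 0.27)
  expect_true("PDH_CIT_ACL" %in% sol$active_routes)
  expect_false("XPK" %in% names(native_network()$reactions))
})

test_that("Xpk/Pta rewiring saves 2.3 moles of glucose (47/3 per triolein)", {
  nat <- min_substrate(yield_problem(native_network()))
  rew <- min_substrate(yield_problem(xpkpta_network()))
  expect_equal(as.character(rew$substrate_per_product), "47/3")
  expect_equal(round(as.numeric(rew$substrate_per_product), 1), 15.7)
  saving <- nat$substrate_per_product - rew$substrate_per_product
  expect_equal(round(as.numeric(saving), 1), 2.3)
  expect_equal(round(rew$mass_yield_g_per_g, 2), 0.31)
  expect_true(all(c("XPK", "PTA") %in% rew$active_routes))
  # the Pfk-deleted rescue strain reaches the same optimum without PFK
  resc <- min_substrate(yield_problem(xpkpta_dpfk_network()))
  expect_true(resc$substrate_per_product == rew$substrate_per_product)
  expect_false("PFK" %in% resc$active_routes)
})

test_that("Pfk deletion without the rescue pathway is NADPH-infeasible", {
  sol <- min_substrate(yield_problem(dpfk_network()))
  expect_equal(sol$status, "infeasible")
  d <- sol$cofactor_diagnosis
  expect_true(d$blocking[d$cofactor == "nadph"])
  expect_equal(d$exact[d$cofactor == "nadph"], "120")
  expect_false(any(d$blocking[d$cofactor != "nadph"]))
  # allowing NADPH overflow restores feasibility (an organism with a
  # cytosolic NADPH oxidase would tolerate the excess)
  rep2 <- feasibility_report(yield_problem(
    dpfk_network(), cofactor_policy = c(nadph = "overflow", nadh = "strict")))
  expect_equal(rep2$status, "feasible")
  # so does adding the Xpk/Pta reactions
  rep3 <- feasibility_report(yield_problem(xpkpta_dpfk_network()))
  expect_equal(rep3$status, "feasible")
  # and the overflow-mode flux is a genuine steady state at 28 glucose
  over <- min_substrate(yield_problem(
    dpfk_network(), cofactor_policy = c(nadph = "overflow", nadh = "strict")))
  expect_equal(as.character(over$substrate_per_product), "28")
})

test_that("zero product demand gives the zero solution", {
  sol <- min_substrate(yield_problem(native_network(), product_amount = 0))
  expect_equal(sol$status, "optimal")
  expect_true(sol$substrate_per_product == oleoflux:::rq(0))
  expect_true(all(sol$flux$n == 0))
})

test_that("the native optimum matches the hand decomposition of routes", {
  # 13.5 glucose -> 27 acetyl-CoA (2 per glucose via glycolysis/PDH/ACL),
  # 4 glucose fully oxidized in the cyclic oxidative PPP (12 NADPH each),
  # 0.5 glucose -> glycerol backbone: 18 total
  expect_equal(27 / 2 + 48 / 12 + 1 / 2, 18)
  net <- native_network()
  sol <- min_substrate(yield_problem(net))
  # the optimal flux realises exactly that carbon split:
  fl <- function(id) unname(as.numeric(sol$flux[match(id, names(sol$flux$n))]))
  expect_equal(fl("GLYC_LOWER"), 27)    # 27 trioses to pyruvate = 13.5 glc
  expect_equal(fl("OXPPP"), 24)         # 24 oxidative turns = 48 NADPH
  expect_equal(fl("G3PDH"), 1)          # one glycerol backbone
  expect_equal(fl("TAGSYN"), 1)
  # carbon closure at the optimum: 18 x 6 = 57 (TAG) + 51 (CO2)
  co2 <- fl("OXPPP") + fl("PDH_CIT_ACL")
  expect_equal(18 * 6, 57 + co2)
})

test_that("an explicit steady-state flux certifies the native optimum", {
  # hand-assembled vector for the 18-glucose solution
  net <- native_network()
  v <- c(ATPM = 473 / 15, FBA = 10, FBPASE = 0, G3PDH = 1, GLK = 18,
         GLYC_LOWER = 27, OXPPP = 24, PDH_CIT_ACL = 27, PFK = 10,
         PGI = -6, RESP = 53, TAGSYN = 1, TKT_TAL = 8, TPI = 9)
  S <- stoichiometric_matrix(net, exact = FALSE)
  net_production <- S[, names(v)] %*% v
  roles <- vapply(net$metabolites, `[[`, character(1), "role")
  internal <- rownames(S)[roles != "exchange"]
  expect_equal(unname(net_production[internal, 1]), rep(0, length(internal)),
               tolerance = 1e-9)
  expect_equal(net_production["glc", 1], -18, ignore_attr = TRUE)
  expect_equal(net_production["tag", 1], 1, ignore_attr = TRUE)
})

test_that("relaxing constraints never worsens the optimum", {
  # overflow on any cofactor can only decrease substrate demand
  for (build in list(native_network, xpkpta_network)) {
    strictv <- min_substrate(yield_problem(build()))
    for (cof in c("nadph", "nadh")) {
      pol <- c(nadph = "strict", nadh = "strict")
      pol[cof] <- "overflow"
      relaxed <- min_substrate(yield_problem(build(), cofactor_policy = pol))
      expect_true(relaxed$substrate_per_product <= strictv$substrate_per_product,
                  info = cof)
    }
    ign <- min_substrate(yield_problem(build(), atp_policy = "ignored"))
    expect_true(ign$substrate_per_product <= strictv$substrate_per_product)
  }
  # adding reactions (dpfk -> +XPK/PTA -> +PFK back) never increases demand
  a <- min_substrate(yield_problem(xpkpta_dpfk_network()))
  b <- min_substrate(yield_problem(xpkpta_network()))
  expect_true(b$substrate_per_product <= a$substrate_per_product)
})

test_that("yield responds to the respiration and TAG configuration", {
  # with ATP ignored only the backbone NADH constrains redox, and reverse
  # transketolase can feed phosphoketolase: 163/12 glucose
  # (26.5 AcP-derived + 0.5 ACL-derived acetyl-CoA; checked by hand)
  sol <- min_substrate(yield_problem(xpkpta_network(), atp_policy = "ignored"))
  expect_equal(as.character(sol$substrate_per_product), "163/12")
  expect_true(sol$substrate_per_product < oleoflux:::rq(47, 3))
  # the sink is generated from the TAG spec: tripalmitin propagates through
  tp <- min_substrate(yield_problem(native_network(tag = "16:0/16:0/16:0")))
  # 24 acetyl-CoA (12 glc) + 42 NADPH (3.5 glc) + 0.5 backbone = 16 glc
  expect_equal(as.character(tp$substrate_per_product), "16")
  expect_equal(unname(tag_formula("16:0/16:0/16:0")["C"]), 51L)
})

test_that("max_mass_yield rounds as requested and flags infeasibility", {
  expect_equal(max_mass_yield(yield_problem(native_network()), digits = 2), 0.27)
  expect_equal(max_mass_yield(yield_problem(xpkpta_network()), digits = 2), 0.31)
  expect_true(is.na(max_mass_yield(yield_problem(dpfk_network()))))
  expect_error(max_mass_yield(yield_problem(toy_chain_network(), "A", "C")),
               "formula")
})
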