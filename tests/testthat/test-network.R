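test_that("network validation catches structural errors", {
  expect_error(reaction("R", numeric()), "nonempty")
  expect_error(reaction("R", c(A = 0)), "zero coefficients")
  expect_error(reaction("R", c(A = -1, B = 1), enzyme = "NOPE"), "vocabulary")
  mets <- list(metabolite("A", role = "exchange"), metabolite("B"))
  expect_error(
    reaction_network("bad", mets, list(reaction("R", c(A = -1, foo = 1)))),
    "undeclared metabolite.*foo")
  expect_error(
    reaction_network("bad", list(metabolite("A"), metabolite("A")),
                     list(reaction("R", c(A = -1)))),
    "duplicated metabolite")
  expect_error(
    reaction_network("bad", list(metabolite("A")),
                     list(reaction("R", c(A = -1)))),
    "exchange")
})

test_that("stoichiometric matrix holds signed rational coefficients", {
  net <- reaction_network(
    "ab", list(metabolite("A", role = "exchange"), metabolite("B")),
    list(reaction("R1", c(A = -1, B = 1))))
  S <- stoichiometric_matrix(net, exact = FALSE)
  expect_equal(S[, "R1"], c(A = -1, B = 1))
  # phosphotransacetylase column: AcP consumed, acetyl-CoA formed
  nat <- xpkpta_network()
  S2 <- stoichiometric_matrix(nat, exact = FALSE)
  expect_equal(S2["acp", "PTA"], -1)
  expect_equal(S2["accoa", "PTA"], 1)
  expect_equal(S2["acp", "XPK"], 1)
  # zero flux gives zero net production everywhere
  Se <- stoichiometric_matrix(nat)
  v0 <- oleoflux:::rq_zeros(ncol(Se$n))
  expect_true(all(oleoflux:::rq_matvec(Se, v0)$n == 0))
  # degenerate case: no reactions
  empty <- reaction_network("empty", list(metabolite("A", role = "exchange")),
                            list())
  expect_equal(ncol(stoichiometric_matrix(empty, exact = FALSE)), 0L)
})

test_that("elemental balance checking reports imbalances and unknowns", {
  mets <- list(metabolite("glc", formula = "C6H12O6", role = "exchange"),
               metabolite("triose", formula = "C3H6O3"),
               metabolite("co2", formula = "CO2", role = "exchange"),
               metabolite("mystery", role = "internal"))
  net <- reaction_network("t", mets, list(
    reaction("SPLIT", c(glc = -1, triose = 2)),
    reaction("BURN", c(glc = -1, co2 = 1)),
    reaction("UNK", c(glc = -1, mystery = 1))))
  out <- check_elemental_balance(net)
  expect_false("SPLIT" %in% out$reaction)
  burn <- out[out$reaction == "BURN" & out$element == "C", ]
  expect_equal(burn$imbalance, -5)
  unk <- out[out$reaction == "UNK", ]
  expect_match(unk$note, "unable to check")
  expect_true(is.na(unk$imbalance))
})

test_that("packaged fixtures are carbon-balanced with lumped steps exempt", {
  for (net in all_fixture_networks()) {
    expect_identical(nrow(check_elemental_balance(net)), 0L)
  }
  # independent bookkeeping: sum formula carbon weighted by coefficients
  net <- native_network()
  S <- stoichiometric_matrix(net, exact = FALSE)
  carbons <- vapply(net$metabolites, function(m)
    if (is.null(m$formula)) NA_real_ else oleoflux:::formula_count(m$formula, "C"),
    numeric(1))
  roles <- vapply(net$metabolites, `[[`, character(1), "role")
  for (rid in names(net$reactions)) {
    rxn <- net$reactions[[rid]]
    if ("lumped" %in% rxn$tags) next
    ids <- names(rxn$stoich$n)
    ids <- ids[roles[ids] != "cofactor_pair_member"]
    if (!length(ids) || anyNA(carbons[ids])) next
    expect_equal(sum(S[ids, rid] * carbons[ids]), 0, info = rid)
  }
})

test_that("network JSON round trip preserves everything exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  for (net in all_fixture_networks()) {
    save_network(net, path)
    back <- load_network(path)
    expect_identical(met_sig <- lapply(back$metabolites, function(m)
      list(m$id, m$role, if (is.null(m$formula)) NA else format(m$formula))),
      lapply(net$metabolites, function(m)
        list(m$id, m$role, if (is.null(m$formula)) NA else format(m$formula))))
    expect_identical(names(back$reactions), names(net$reactions))
    for (rid in names(net$reactions)) {
      a <- net$reactions[[rid]]; b <- back$reactions[[rid]]
      expect_identical(as.character(b$stoich), as.character(a$stoich))
      expect_identical(names(b$stoich$n), names(a$stoich$n))
      expect_identical(b$reversible, a$reversible)
      expect_identical(b$enzyme, a$enzyme)
      expect_identical(sort(b$tags), sort(a$tags))
    }
    # double round trip produces byte-identical files
    path2 <- withr::local_tempfile(fileext = ".json")
    save_network(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("installed JSON fixtures match the in-code builders", {
  for (nm in oleoflux_fixture()) {
    from_file <- load_network(oleoflux_fixture(nm))
    built <- fixture_builders_for_test(nm)
    expect_identical(names(from_file$reactions), names(built$reactions))
    for (rid in names(built$reactions)) {
      expect_identical(as.character(from_file$reactions[[rid]]$stoich),
                       as.character(built$reactions[[rid]]$stoich))
    }
  }
})

test_that("malformed network files fail loudly", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", p)
  expect_error(load_network(p), "malformed JSON")
  writeLines('{"name": "x", "metabolites": []}', p)
  expect_error(load_network(p), "reactions")
  writeLines('{"name":"x","metabolites":[{"id":"A","role":"exchange"}],
    "reactions":[{"id":"R","stoich":{"A":-1,"foo":1}}]}', p)
  expect_error(load_network(p), "undeclared metabolite")
  expect_error(load_network(tempfile()), "no such network file")
})
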