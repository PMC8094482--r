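# small fixtures built in code for the LP and codon tests

# linear chain A -> B -> C, one unit of A per unit of C
toy_chain_network <- function() {
  reaction_network(
    "chain",
    list(metabolite("A", role = "exchange"),
         metabolite("B"),
         metabolite("C", role = "exchange")),
    list(reaction("R1", c(A = -1, B = 1)),
         reaction("R2", c(B = -1, C = 1)))
  )
}

# two routes to the product costing 2 and 3 substrate
toy_two_route_network <- function() {
  reaction_network(
    "two-routes",
    list(metabolite("S", role = "exchange"),
         metabolite("P", role = "exchange")),
    list(reaction("CHEAP", c(S = -2, P = 1)),
         reaction("DEAR", c(S = -3, P = 1)))
  )
}

# product demands a cofactor no reaction regenerates
toy_blocked_network <- function() {
  reaction_network(
    "blocked",
    list(metabolite("S", role = "exchange"),
         metabolite("P", role = "exchange"),
         metabolite("red", role = "cofactor_pair_member")),
    list(reaction("MAKE", c(S = -1, P = 1, red = 1)))
  )
}

# seeded random small network over {S, A, B, P}; always contains a working
# route S -> A -> P, plus a few random side reactions (possibly reversible)
random_small_network <- function(seed) {
  mets <- list(metabolite("S", role = "exchange"),
               metabolite("A"), metabolite("B"),
               metabolite("P", role = "exchange"))
  ids <- c("S", "A", "B", "P")
  rxns <- list(
    reaction("BASE1", c(S = -1, A = sample(1:2, 1))),
    reaction("BASE2", c(A = -sample(1:2, 1), P = 1))
  )
  n_extra <- sample(2:5, 1)
  for (k in seq_len(n_extra)) {
    picked <- sample(ids, sample(2:3, 1))
    coef <- sample(c(-2, -1, 1, 2), length(picked), replace = TRUE)
    if (all(coef > 0)) coef[1] <- -coef[1]
    if (all(coef < 0)) coef[length(coef)] <- -coef[length(coef)]
    st <- stats::setNames(coef, picked)
    rxns[[length(rxns) + 1L]] <- reaction(paste0("X", k), st,
                                          reversible = sample(c(TRUE, FALSE), 1))
  }
  reaction_network(paste0("random-", seed), mets, rxns)
}

fixture_builders_for_test <- function(nm) {
  oleoflux:::fixture_builders()[[nm]]()
}

# every fixture builder shipped by the package
all_fixture_networks <- function() {
  list(native = native_network(),
       dpfk_ppp_only = dpfk_network(),
       xpkpta = xpkpta_network(),
       xpkpta_dpfk = xpkpta_dpfk_network())
}

# hand-built usage table: uniform within each family except engineered
# rare codons (TTA, CTA in the leucine family; GGG in the glycine family)
toy_usage_table <- function() {
  code <- oleoflux:::standard_code()
  sc <- oleoflux:::sense_codons()
  aa <- code[sc]
  frac <- stats::ave(rep(1, length(sc)), aa, FUN = function(v) v / length(v))
  tab <- data.frame(codon = sc, amino_acid = unname(aa), fraction = frac)
  set_frac <- function(tab, codon, f) { tab$fraction[tab$codon == codon] <- f; tab }
  tab <- set_frac(tab, "CTG", 0.50); tab <- set_frac(tab, "CTC", 0.28)
  tab <- set_frac(tab, "CTT", 0.10); tab <- set_frac(tab, "TTG", 0.10)
  tab <- set_frac(tab, "TTA", 0.01); tab <- set_frac(tab, "CTA", 0.01)
  tab <- set_frac(tab, "GGC", 0.50); tab <- set_frac(tab, "GGT", 0.40)
  tab <- set_frac(tab, "GGA", 0.08); tab <- set_frac(tab, "GGG", 0.02)
  codon_usage_table(tab)
}

# random CDS of `n` codons (ATG + random sense codons + TAA)
random_cds <- function(n = 30) {
  sc <- oleoflux:::sense_codons()
  coding_sequence(paste(c("ATG", sample(sc, n, replace = TRUE), "TAA"),
                        collapse = ""))
}
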