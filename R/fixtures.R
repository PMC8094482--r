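#' Packaged central-carbon networks
#'
#' Builders for the four strain networks analysed by the package: the native
#' glucose-to-lipid pathway of an oleaginous yeast (glycolysis + pyruvate
#' dehydrogenase + ATP:citrate lyase for cytosolic acetyl-CoA, oxidative
#' pentose phosphate pathway for NADPH), the phosphofructokinase deletion,
#' and the phosphoketolase/phosphotransacetylase (Xpk/Pta) rewiring in both
#' backgrounds. Mitochondrial steps are lumped into single cytosolic-
#' effective routes, cofactor pairs are represented by their reduced member,
#' and NADH/ATP close through a lumped respiration step (see the methods
#' vignette for the conventions and the respiration calibration).
#'
#' The same networks ship as JSON fixtures under `inst/extdata` (see
#' [oleoflux_fixture()]); builders and files are tested to agree.
#'
#' @name fixtures
NULL

core_metabolites <- function(tag = triolein()) {
  list(
    metabolite("glc",   "glucose",                    "C6H12O6", role = "exchange"),
    metabolite("g6p",   "glucose 6-phosphate",        "C6H12O6"),
    metabolite("f6p",   "fructose 6-phosphate",       "C6H12O6"),
    metabolite("fbp",   "fructose 1,6-bisphosphate",  "C6H12O6"),
    metabolite("dhap",  "dihydroxyacetone phosphate", "C3H6O3"),
    metabolite("ga3p",  "glyceraldehyde 3-phosphate", "C3H6O3"),
    metabolite("pyr",   "pyruvate",                   "C3H4O3"),
    metabolite("p5p",   "pentose 5-phosphate pool",   "C5H10O5"),
    metabolite("acp",   "acetyl phosphate",           "C2H4O2"),
    metabolite("accoa", "acetyl-CoA (acetyl moiety)", "C2H3O"),
    metabolite("gly3p", "glycerol 3-phosphate",       "C3H8O3"),
    metabolite("tag",   "triacylglycerol",            tag_formula(tag),
               role = "exchange"),
    metabolite("co2",   "carbon dioxide",             "CO2", role = "exchange"),
    metabolite("nadph", "NADPH (pair member)",        role = "cofactor_pair_member"),
    metabolite("nadh",  "NADH (pair member)",         role = "cofactor_pair_member"),
    metabolite("atp",   "ATP (pair member)",          role = "cofactor_pair_member")
  )
}

core_reactions <- function(tag = triolein()) {
  list(
    reaction("GLK", c(glc = -1, atp = -1, g6p = 1), enzyme = "GLK",
             tags = "native"),
    reaction("PGI", c(g6p = -1, f6p = 1), enzyme = "PGI", reversible = TRUE,
             tags = "native"),
    reaction("PFK", c(f6p = -1, atp = -1, fbp = 1), enzyme = "PFK",
             tags = "native"),
    reaction("FBA", c(fbp = -1, dhap = 1, ga3p = 1), enzyme = "FBA",
             reversible = TRUE, tags = "native"),
    reaction("TPI", c(dhap = -1, ga3p = 1), enzyme = "TPI", reversible = TRUE,
             tags = "native"),
    reaction("FBPASE", c(fbp = -1, f6p = 1), enzyme = "FBP", tags = "native"),
    # lower glycolysis lump: Ga3P -> pyruvate (+ NADH from GAPDH, + 2 ATP)
    reaction("GLYC_LOWER", c(ga3p = -1, pyr = 1, nadh = 1, atp = 2),
             enzyme = "PYK", tags = c("native", "lumped")),
    # mitochondrial route lump: PDH + citrate synthase + ATP:citrate lyase,
    # pyruvate -> cytosolic acetyl-CoA at 1 ATP, releasing CO2 and NADH
    reaction("PDH_CIT_ACL", c(pyr = -1, atp = -1, accoa = 1, co2 = 1, nadh = 1),
             enzyme = "ACL", tags = c("native", "lumped")),
    # oxidative PPP lump: G6P -> pentose-P + CO2 + 2 NADPH
    reaction("OXPPP", c(g6p = -1, p5p = 1, co2 = 1, nadph = 2),
             enzyme = "ZWF", tags = c("native", "lumped")),
    # non-oxidative PPP lump (transketolase/transaldolase)
    reaction("TKT_TAL", c(p5p = -3, f6p = 2, ga3p = 1), enzyme = "TKT",
             reversible = TRUE, tags = c("native", "lumped")),
    # glycerol backbone: DHAP + NADH -> glycerol 3-phosphate
    reaction("G3PDH", c(dhap = -1, nadh = -1, gly3p = 1), enzyme = "GPD",
             tags = "native"),
    # lumped respiration; the ATP coefficient is the effective P/O ratio and
    # is overridden by yield_problem()'s atp_per_nadh
    reaction("RESP", list(nadh = -1, atp = "16/15"),
             tags = c("lumped", "respiration")),
    # non-growth ATP drain (maintenance ATPase)
    reaction("ATPM", c(atp = -1), tags = "maintenance"),
    tag_sink_reaction(tag)
  )
}

#' @describeIn fixtures native network (glycolysis + PDH/ACL + PPP).
#' @param tag target TAG for the synthesis sink (default triolein).
#' @export
native_network <- function(tag = triolein()) {
  reaction_network("native", core_metabolites(tag), core_reactions(tag))
}

#' @describeIn fixtures phosphofructokinase deletion without the rescue
#'   pathway (PPP-only route to triose phosphate).
#' @export
dpfk_network <- function(tag = triolein()) {
  apply_edits(native_network(tag), list(variant_edit("knockout", "PFK")))
}

#' @describeIn fixtures native network plus the heterologous Xpk/Pta
#'   pathway.
#' @export
xpkpta_network <- function(tag = triolein()) {
  apply_edits(native_network(tag),
              list(variant_edit("add_reaction", xpk_reaction()),
                   variant_edit("add_reaction", pta_reaction())))
}

#' @describeIn fixtures Xpk/Pta pathway in the phosphofructokinase-deleted
#'   background (the engineered rescue strain).
#' @export
xpkpta_dpfk_network <- function(tag = triolein()) {
  apply_edits(xpkpta_network(tag), list(variant_edit("knockout", "PFK")))
}

fixture_builders <- function() {
  list(
    native = native_network,
    dpfk_ppp_only = dpfk_network,
    xpkpta = xpkpta_network,
    xpkpta_dpfk = xpkpta_dpfk_network
  )
}

#' Path to a packaged network fixture
#'
#' @param name one of `"native"`, `"dpfk_ppp_only"`, `"xpkpta"`,
#'   `"xpkpta_dpfk"`; `NULL` lists the available names.
#' @return file path into the installed package.
#' @examples
#' net <- load_network(oleoflux_fixture("native"))
#' @export
oleoflux_fixture <- function(name = NULL) {
  avail <- names(fixture_builders())
  if (is.null(name)) return(avail)
  if (!name %in% avail)
    stop("unknown fixture '", name, "'; available: ",
         paste(avail, collapse = ", "))
  system.file("extdata", paste0(name, ".json"), package = "oleoflux",
              mustWork = TRUE)
}
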