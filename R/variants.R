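#' Strain-network variants
#'
#' Engineering edits (enzyme knockouts, heterologous reaction additions)
#' applied to a base network, and side-by-side yield comparison of the
#' resulting variants - mirroring the wild type -> Pfk deletion ->
#' Xpk/Pta rescue engineering narrative.
#'
#' @name pathway_variants
NULL

#' Define a network edit
#'
#' @param kind `"knockout"` (remove all reactions carrying an enzyme label)
#'   or `"add_reaction"`.
#' @param target for knockouts, an enzyme label (e.g. `"PFK"`); for
#'   additions, a [reaction()] object.
#' @return object of class `variant_edit`.
#' @export
variant_edit <- function(kind = c("knockout", "add_reaction"), target) {
  kind <- match.arg(kind)
  if (kind == "knockout") {
    if (!is.character(target) || length(target) != 1L)
      stop("knockout target must be a single enzyme label")
  } else if (!inherits(target, "reaction")) {
    stop("add_reaction target must be a reaction object")
  }
  structure(list(kind = kind, target = target), class = "variant_edit")
}

#' Apply edits to a base network
#'
#' Pure: returns a new network, the base is unchanged. A knockout removes
#' every reaction carrying the target enzyme label and errors if none
#' exists; an addition errors on a duplicated reaction id.
#'
#' @param base a [reaction_network()].
#' @param edits list of [variant_edit()] objects.
#' @return the edited [reaction_network()].
#' @examples
#' dpfk <- apply_edits(native_network(), list(variant_edit("knockout", "PFK")))
#' @export
apply_edits <- function(base, edits) {
  stopifnot(inherits(base, "reaction_network"))
  if (inherits(edits, "variant_edit")) edits <- list(edits)
  rxns <- base$reactions
  for (e in edits) {
    if (!inherits(e, "variant_edit")) stop("edits must be variant_edit objects")
    if (e$kind == "knockout") {
      hit <- vapply(rxns, function(r) identical(r$enzyme, e$target), logical(1))
      if (!any(hit))
        stop("knockout target '", e$target, "' not present in network '",
             base$name, "'")
      rxns <- rxns[!hit]
    } else {
      if (e$target$id %in% names(rxns))
        stop("cannot add reaction '", e$target$id, "': id already present")
      rxns[[e$target$id]] <- e$target
    }
  }
  reaction_network(base$name, unname(base$metabolites), unname(rxns))
}

#' Heterologous phosphoketolase reaction
#'
#' Cleaves a sugar phosphate into acetyl phosphate plus a shorter sugar
#' phosphate. The pentose-phosphate substrate (X5P, drawn from the lumped
#' pentose-P pool) is the primary mode; the fructose-6-phosphate mode, whose
#' in-vivo product spectrum is less settled, is available with a
#' configurable second product (textbook erythrose 4-phosphate, or
#' glyceraldehyde 3-phosphate).
#'
#' @param substrate `"x5p"` (default) or `"f6p"`.
#' @param f6p_product second product of the F6P mode: `"e4p"` or `"ga3p"`.
#'   Networks using the E4P mode must declare an `e4p` metabolite.
#' @return a [reaction()] with enzyme label `XPK`.
#' @export
xpk_reaction <- function(substrate = c("x5p", "f6p"),
                         f6p_product = c("e4p", "ga3p")) {
  substrate <- match.arg(substrate)
  if (substrate == "x5p") {
    return(reaction("XPK", c(p5p = -1, acp = 1, ga3p = 1), enzyme = "XPK",
                    tags = "heterologous"))
  }
  f6p_product <- match.arg(f6p_product)
  reaction("XPK_F6P", stats::setNames(c(-1, 1, 1), c("f6p", "acp", f6p_product)),
           enzyme = "XPK", tags = "heterologous")
}

#' Heterologous phosphotransacetylase reaction
#'
#' Reversible conversion of acetyl phosphate to acetyl-CoA (CoA and
#' phosphate implicit).
#'
#' @return a [reaction()] with enzyme label `PTA`.
#' @export
pta_reaction <- function() {
  reaction("PTA", c(acp = -1, accoa = 1), enzyme = "PTA", reversible = TRUE,
           tags = "heterologous")
}

#' Compare yield outcomes across network variants
#'
#' Runs [min_substrate()] for the same TAG on each variant and tabulates
#' feasibility, moles of substrate per mole TAG, mass yield and the blocking
#' cofactor for infeasible variants. Row order follows the input order.
#'
#' @param variants named list of at least two [reaction_network()]s.
#' @param tag a [tag_spec()] or TAG string.
#' @param substrate,product,... passed to [yield_problem()].
#' @return data.frame with one row per variant.
#' @examples
#' compare_variants(list(native = native_network(),
#'                       rewired = xpkpta_network()))
#' @export
compare_variants <- function(variants, tag = triolein(),
                             substrate = "glc", product = "tag", ...) {
  if (!is.list(variants) || length(variants) < 2L)
    stop("need at least two variants to compare")
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop("variants must be named")
  rows <- lapply(names(variants), function(nm) {
    net <- variants[[nm]]
    sol <- min_substrate(yield_problem(net, substrate, product, ...))
    if (sol$status == "optimal") {
      data.frame(variant = nm, status = "feasible",
                 substrate_per_product = as.numeric(sol$substrate_per_product),
                 substrate_per_product_exact = as.character(sol$substrate_per_product),
                 mass_yield_g_per_g = if (is.null(sol$mass_yield_g_per_g))
                   NA_real_ else sol$mass_yield_g_per_g,
                 blocking_cofactor = NA_character_)
    } else {
      d <- sol$cofactor_diagnosis
      blk <- d$cofactor[which(d$blocking)]
      data.frame(variant = nm, status = "infeasible",
                 substrate_per_product = NA_real_,
                 substrate_per_product_exact = NA_character_,
                 mass_yield_g_per_g = NA_real_,
                 blocking_cofactor = if (length(blk)) paste(blk, collapse = ",")
                                     else NA_character_)
    }
  })
  do.call(rbind, rows)
}
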