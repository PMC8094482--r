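#' Triacylglycerol specifications and precursor demand
#'
#' Fatty acid synthesis assembles acyl chains from two-carbon acetyl units:
#' every chain of length L consumes L/2 acetyl-CoA, of which all but the
#' primer are first carboxylated to malonyl-CoA (one ATP each). Each
#' condensation into the growing C16 chain consumes two NADPH, and each
#' two-carbon elongation of C16 to C18 consumes two more. Desaturation also
#' consumes reduced cofactor, but whether NADH or NADPH is preferred is
#' unsettled, so desaturation is tracked separately and excluded from the
#' NADPH total unless requested.
#'
#' @name lipid_stoichiometry
NULL

#' Acyl chain specification
#'
#' @param carbons even integer chain length (>= 4).
#' @param double_bonds number of C=C double bonds (>= 0, < carbons/2).
#' @return object of class `acyl_chain`.
#' @examples
#' acyl_chain(18, 1) # oleoyl
#' @export
acyl_chain <- function(carbons, double_bonds = 0) {
  if (length(carbons) != 1L || carbons < 4 || carbons != round(carbons))
    stop("carbons must be a single integer >= 4")
  if (carbons %% 2 != 0)
    stop("acyl chains are assembled from acetyl units: carbon count must be even")
  if (double_bonds < 0 || double_bonds != round(double_bonds))
    stop("double_bonds must be a non-negative integer")
  if (double_bonds >= carbons / 2)
    stop("double_bonds must be < carbons/2")
  structure(list(carbons = as.integer(carbons), double_bonds = as.integer(double_bonds)),
            class = "acyl_chain")
}

#' Triacylglycerol specification
#'
#' @param chains a list of exactly three [acyl_chain()] objects, or a string
#'   such as `"18:1/18:1/18:1"` (carbons:double_bonds for each sn position).
#' @return object of class `tag_spec`.
#' @examples
#' tag_spec("18:1/18:1/18:1")
#' @export
tag_spec <- function(chains) {
  if (inherits(chains, "tag_spec")) return(chains)
  if (is.character(chains)) return(parse_tag(chains))
  if (inherits(chains, "acyl_chain")) chains <- list(chains)
  if (!is.list(chains) || length(chains) != 3L ||
      !all(vapply(chains, inherits, logical(1), "acyl_chain")))
    stop("a triacylglycerol has exactly three acyl chains")
  structure(list(chains = chains), class = "tag_spec")
}

#' Parse a TAG string like "18:1/18:1/18:1"
#'
#' @param x character scalar, three `carbons:double_bonds` tokens separated
#'   by `/`.
#' @return a [tag_spec()].
#' @export
parse_tag <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- strsplit(trimws(x), "/", fixed = TRUE)[[1]]
  if (length(toks) != 3L) stop("a triacylglycerol has exactly three acyl chains: ", x)
  chains <- lapply(toks, function(t) {
    if (!grepl("^\\s*[0-9]+:[0-9]+\\s*$", t)) stop("malformed chain token: ", t)
    p <- as.numeric(strsplit(trimws(t), ":", fixed = TRUE)[[1]])
    acyl_chain(p[1], p[2])
  })
  tag_spec(chains)
}

#' Triolein (three C18:1 chains)
#' @return a [tag_spec()].
#' @export
triolein <- function() parse_tag("18:1/18:1/18:1")

#' @export
format.tag_spec <- function(x, ...) {
  paste(vapply(x$chains, function(ch) paste0(ch$carbons, ":", ch$double_bonds),
               character(1)), collapse = "/")
}

#' @export
print.tag_spec <- function(x, ...) {
  cat("<TAG> ", format(x), " = ", format(tag_formula(x)), "\n", sep = "")
  invisible(x)
}

chain_carbons <- function(tag) vapply(tag$chains, function(ch) ch$carbons, integer(1))
chain_dbs     <- function(tag) vapply(tag$chains, function(ch) ch$double_bonds, integer(1))

#' Acetyl-CoA demand of a triacylglycerol
#'
#' Moles of acetyl-CoA needed per mole of TAG: each chain of length L is
#' assembled from L/2 two-carbon units. Triolein (3 x C18:1) needs 27.
#'
#' @param tag a [tag_spec()] or TAG string.
#' @return integer moles acetyl-CoA per mole TAG.
#' @examples
#' acetyl_demand(triolein()) # 27
#' @export
acetyl_demand <- function(tag) {
  tag <- tag_spec(tag)
  as.integer(sum(chain_carbons(tag)) / 2L)
}

#' Malonyl-CoA demand of a triacylglycerol
#'
#' Every acetyl unit except each chain's primer enters as malonyl-CoA
#' (one ATP each via acetyl-CoA carboxylase).
#'
#' @inheritParams acetyl_demand
#' @return integer moles malonyl-CoA per mole TAG.
#' @export
malonyl_demand <- function(tag) {
  tag <- tag_spec(tag)
  acetyl_demand(tag) - length(tag$chains)
}

#' Precursor and cofactor demand of a triacylglycerol
#'
#' Applies the two stated cofactor rules: 2 NADPH per acetyl-unit
#' condensation into the growing C16 chain (7 condensations for a C16, hence
#' 14 NADPH), and 2 NADPH per two-carbon elongation beyond C16. Chains
#' shorter than C16 use the condensation rule only. Desaturation cofactor is
#' reported separately and excluded from `nadph_total` by default because
#' the preferred desaturase cofactor (NADH vs NADPH) is unsettled.
#'
#' @inheritParams acetyl_demand
#' @param include_desaturation if `TRUE`, add the desaturation line item to
#'   `nadph_total`.
#' @param desaturation_cofactor_cost reduced-cofactor cost per double bond.
#' @return object of class `precursor_demand` with integer fields
#'   `acetyl_coa`, `malonyl_coa`, `nadph_condensation`, `nadph_elongation`,
#'   `nadph_desaturation`, `nadph_total`, `glycerol_backbone_c3` and
#'   `atp_carboxylation`.
#' @examples
#' precursor_demand(triolein()) # 27 acetyl-CoA, 48 NADPH
#' @export
precursor_demand <- function(tag, include_desaturation = FALSE,
                             desaturation_cofactor_cost = 1L) {
  tag <- tag_spec(tag)
  L <- chain_carbons(tag)
  cond <- ifelse(L >= 16, 2L * (16L / 2L - 1L), 2L * (L / 2L - 1L))
  elong <- ifelse(L >= 16, 2L * (L - 16L) / 2L, 0L)
  desat <- chain_dbs(tag) * desaturation_cofactor_cost
  out <- list(
    tag = tag,
    acetyl_coa = acetyl_demand(tag),
    malonyl_coa = malonyl_demand(tag),
    nadph_condensation = as.integer(sum(cond)),
    nadph_elongation = as.integer(sum(elong)),
    nadph_desaturation = as.integer(sum(desat)),
    include_desaturation = include_desaturation,
    glycerol_backbone_c3 = 1L,
    atp_carboxylation = malonyl_demand(tag)
  )
  out$nadph_total <- out$nadph_condensation + out$nadph_elongation +
    if (include_desaturation) out$nadph_desaturation else 0L
  structure(out, class = "precursor_demand")
}

#' @export
print.precursor_demand <- function(x, ...) {
  cat("<precursor demand per mole TAG ", format(x$tag), ">\n", sep = "")
  cat("  acetyl-CoA:        ", x$acetyl_coa, "\n")
  cat("  malonyl-CoA:       ", x$malonyl_coa, " (", x$atp_carboxylation, " ATP)\n", sep = "")
  cat("  NADPH condensation:", x$nadph_condensation, "\n")
  cat("  NADPH elongation:  ", x$nadph_elongation, "\n")
  cat("  NADPH desaturation:", x$nadph_desaturation,
      if (x$include_desaturation) " (included)" else " (excluded)", "\n", sep = " ")
  cat("  NADPH total:       ", x$nadph_total, "\n")
  cat("  glycerol backbone:  1 x C3\n")
  invisible(x)
}

#' NADPH demand of a triacylglycerol
#'
#' Convenience wrapper around [precursor_demand()] returning the NADPH total.
#' Triolein with desaturation excluded needs 48.
#'
#' @inheritParams precursor_demand
#' @return integer moles NADPH per mole TAG, with the full
#'   [precursor_demand()] object attached as attribute `"breakdown"`.
#' @examples
#' nadph_demand(triolein()) # 48
#' @export
nadph_demand <- function(tag, include_desaturation = FALSE,
                         desaturation_cofactor_cost = 1L) {
  d <- precursor_demand(tag, include_desaturation, desaturation_cofactor_cost)
  structure(d$nadph_total, breakdown = d)
}

#' Molecular formula of a triacylglycerol
#'
#' Glycerol ester of the three chains: C = 3 + sum of chain carbons,
#' H = 2 + sum over chains of (2L - 2d), O = 6.
#'
#' @inheritParams acetyl_demand
#' @return a [mol_formula()].
#' @examples
#' tag_formula(triolein()) # C57H104O6
#' @export
tag_formula <- function(tag) {
  tag <- tag_spec(tag)
  L <- chain_carbons(tag); d <- chain_dbs(tag)
  mol_formula(c(C = 3 + sum(L), H = 8 + sum(2 * L - 2 * d) - 6, O = 6))
}

#' Mass yield from molar amounts
#'
#' Converts a molar substrate-to-product ratio into a mass yield:
#' (moles product x MW product) / (moles substrate x MW substrate).
#'
#' @param moles_substrate moles of substrate consumed (> 0).
#' @param substrate_formula substrate [mol_formula()] or string.
#' @param moles_product moles of product formed.
#' @param product_formula product [mol_formula()] or string.
#' @return g product per g substrate (full precision; round for reporting).
#' @examples
#' mass_yield(18, "C6H12O6", 1, "C57H104O6")   # ~0.273
#' @export
mass_yield <- function(moles_substrate, substrate_formula,
                       moles_product, product_formula) {
  ms <- if (is.rq(moles_substrate)) as.numeric(moles_substrate) else moles_substrate
  mp <- if (is.rq(moles_product)) as.numeric(moles_product) else moles_product
  if (!is.finite(ms) || ms <= 0) stop("moles_substrate must be > 0")
  (mp * molar_mass(product_formula)) / (ms * molar_mass(substrate_formula))
}
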