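#' Stoichiometric reaction networks
#'
#' A network is a list of metabolites and reactions with exact rational
#' stoichiometric coefficients. Modelling conventions (documented in the
#' methods vignette and the JSON format notes):
#' cofactor pairs (NADPH/NADP+, NADH/NAD+, ATP/ADP) are represented by their
#' reduced/charged member only; water, protons, inorganic phosphate and free
#' CoA are omitted; metabolite formulas describe the carbon skeleton of the
#' species, so elemental balance checks skip H and O by default and skip
#' cofactor-pair members entirely.
#'
#' @name network_core
NULL

# enzyme vocabulary: pathway enzymes plus auxiliary lumped steps
ENZYME_VOCAB <- c(
  "ACC", "ACL", "CIT", "DGA", "ELO", "FAS", "FBA", "FBP", "GLK", "GPD",
  "OLE", "PDH", "PFK", "PGI", "PTA", "PYK", "TAL", "TKT", "TPI", "XPK", "ZWF"
)

MET_ROLES <- c("internal", "exchange", "cofactor_pair_member")

#' Define a metabolite
#'
#' @param id short unique identifier (e.g. `"g6p"`).
#' @param name human-readable name.
#' @param formula optional [mol_formula()] or formula string for the carbon
#'   skeleton of the species (used by [check_elemental_balance()]).
#' @param role one of `"internal"`, `"exchange"`,
#'   `"cofactor_pair_member"`. Only exchange metabolites may have nonzero
#'   net production or consumption at steady state.
#' @return object of class `metabolite`.
#' @export
metabolite <- function(id, name = id, formula = NULL,
                       role = c("internal", "exchange", "cofactor_pair_member")) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("metabolite id must be a non-empty string")
  if (!is.null(formula)) formula <- mol_formula(formula)
  structure(list(id = id, name = name, formula = formula, role = role),
            class = "metabolite")
}

#' Define a reaction
#'
#' @param id unique reaction identifier.
#' @param stoich named vector or list of signed coefficients
#'   (negative = consumed). Values may be numeric integers, `"num/den"`
#'   strings, or `rq` rationals. Zero coefficients are not stored.
#' @param enzyme optional enzyme label from the declared vocabulary
#'   (e.g. `"PFK"`, `"XPK"`).
#' @param reversible logical; irreversible reactions carry non-negative flux.
#' @param tags character tags (e.g. `"native"`, `"heterologous"`,
#'   `"lumped"`, `"respiration"`, `"maintenance"`, `"sink"`).
#' @return object of class `reaction`.
#' @export
reaction <- function(id, stoich, enzyme = NULL, reversible = FALSE,
                     tags = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("reaction id must be a non-empty string")
  if (length(stoich) == 0L) stop("reaction ", id, ": stoichiometry must be nonempty")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction ", id, ": stoichiometry must be named by metabolite id")
  if (anyDuplicated(names(stoich)))
    stop("reaction ", id, ": duplicated metabolite in stoichiometry")
  coef <- if (is.list(stoich)) {
    do.call(rq_c, lapply(stoich, function(v) if (is.rq(v)) v else rq_parse(v)))
  } else rq_parse(stoich)
  names(coef$n) <- names(stoich)
  if (any(coef$n == 0)) stop("reaction ", id, ": zero coefficients are not stored")
  if (!is.null(enzyme)) {
    if (!enzyme %in% ENZYME_VOCAB)
      stop("reaction ", id, ": enzyme label '", enzyme,
           "' not in declared vocabulary")
  }
  structure(list(id = id, enzyme = enzyme, stoich = coef,
                 reversible = isTRUE(reversible), tags = as.character(tags)),
            class = "reaction")
}

reaction_met_ids <- function(rxn) names(rxn$stoich$n)

#' Assemble a reaction network
#'
#' Validates that metabolite ids are unique, every referenced metabolite is
#' declared, and at least one exchange metabolite exists.
#'
#' @param name network name.
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @return object of class `reaction_network`.
#' @export
reaction_network <- function(name, metabolites, reactions) {
  stopifnot(is.list(metabolites), is.list(reactions))
  if (!all(vapply(metabolites, inherits, logical(1), "metabolite")))
    stop("metabolites must be metabolite objects")
  if (!all(vapply(reactions, inherits, logical(1), "reaction")))
    stop("reactions must be reaction objects")
  mids <- vapply(metabolites, `[[`, character(1), "id")
  if (anyDuplicated(mids))
    stop("duplicated metabolite id(s): ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicated reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (rxn in reactions) {
    missing <- setdiff(reaction_met_ids(rxn), mids)
    if (length(missing))
      stop("reaction ", rxn$id, " references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  roles <- vapply(metabolites, `[[`, character(1), "role")
  if (!any(roles == "exchange"))
    stop("a network needs at least one exchange metabolite")
  names(metabolites) <- mids
  names(reactions) <- rids
  structure(list(name = name, metabolites = metabolites, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction network> ", x$name, ": ", length(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

met_ids <- function(net) vapply(net$metabolites, `[[`, character(1), "id")
rxn_ids <- function(net) vapply(net$reactions, `[[`, character(1), "id")
met_roles <- function(net) vapply(net$metabolites, `[[`, character(1), "role")

#' Stoichiometric matrix of a network
#'
#' Entry (i, j) is the signed coefficient of metabolite i in reaction j.
#'
#' @param net a [reaction_network()].
#' @param exact if `TRUE` (default) return an exact rational (`rq`) matrix;
#'   otherwise a base numeric matrix. Row/column names are carried in
#'   attribute `dimnames` of the numerator for the exact form.
#' @return metabolites x reactions matrix.
#' @export
stoichiometric_matrix <- function(net, exact = TRUE) {
  mids <- met_ids(net)
  rids <- rxn_ids(net)
  N <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  D <- matrix(1, length(mids), length(rids), dimnames = list(mids, rids))
  for (j in seq_along(net$reactions)) {
    rxn <- net$reactions[[j]]
    ids <- reaction_met_ids(rxn)
    N[ids, j] <- rxn$stoich$n
    D[ids, j] <- rxn$stoich$d
  }
  if (!exact) return(N / D)
  structure(list(n = N, d = D), class = "rq")
}

#' Check elemental balance of network reactions
#'
#' Sums formula-weighted coefficients per element for every checked
#' reaction. Metabolites with role `cofactor_pair_member` are skipped (their
#' implicit oxidized partner carries the complementary atoms); H and O are
#' skipped by default because water and protons are omitted from reactions.
#' A reaction containing a non-cofactor metabolite without a formula yields
#' an explicit "unable to check" row rather than a silent pass.
#'
#' @param net a [reaction_network()].
#' @param elements elements to check; default: all elements appearing in the
#'   network's formulas except H and O.
#' @param exempt_tags reactions carrying any of these tags are skipped
#'   (default `"lumped"` exempts lumped synthesis/respiration steps).
#' @return data.frame with columns `reaction`, `element`, `imbalance`
#'   (signed atom count, NA when unable to check) and `note`; zero rows iff
#'   every checked reaction balances.
#' @export
check_elemental_balance <- function(net, elements = NULL,
                                    exempt_tags = "lumped") {
  roles <- met_roles(net)
  have_formula <- !vapply(net$metabolites, function(m) is.null(m$formula), logical(1))
  if (is.null(elements)) {
    els <- unique(unlist(lapply(net$metabolites[have_formula],
                                function(m) names(m$formula))))
    elements <- setdiff(els, c("H", "O"))
  }
  rows <- list()
  for (rxn in net$reactions) {
    if (length(intersect(rxn$tags, exempt_tags))) next
    ids <- reaction_met_ids(rxn)
    ids <- ids[roles[ids] != "cofactor_pair_member"]
    if (!length(ids)) next
    missing <- ids[!have_formula[ids]]
    if (length(missing)) {
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = rxn$id, element = NA_character_, imbalance = NA_real_,
        note = paste("unable to check: no formula for",
                     paste(missing, collapse = ", ")))
      next
    }
    coef <- as.numeric(rxn$stoich)[match(ids, reaction_met_ids(rxn))]
    for (el in elements) {
      counts <- vapply(net$metabolites[ids],
                       function(m) formula_count(m$formula, el), numeric(1))
      imb <- sum(coef * counts)
      if (abs(imb) > 1e-9) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = rxn$id, element = el, imbalance = imb,
          note = "imbalanced")
      }
    }
  }
  if (!length(rows))
    return(data.frame(reaction = character(), element = character(),
                      imbalance = numeric(), note = character()))
  do.call(rbind, rows)
}

## ---- JSON dialect ---------------------------------------------------------
## top-level keys: name, metabolites [{id, name, formula, role}],
## reactions [{id, enzyme, stoich {met: "num/den" | int}, reversible, tags}]

#' Read a network from its JSON file
#'
#' @param path path to a network JSON file (see the packaged fixtures under
#'   `inst/extdata` for the dialect).
#' @return a validated [reaction_network()].
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such network file: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", path, ": ", conditionMessage(e)))
  for (key in c("name", "metabolites", "reactions"))
    if (is.null(doc[[key]])) stop("network JSON missing required key: '", key, "'")
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry missing required key: 'id'")
    metabolite(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               formula = m$formula,
               role = if (is.null(m$role)) "internal" else m$role)
  })
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry missing required key: 'id'")
    if (is.null(r$stoich)) stop("reaction ", r$id, " missing required key: 'stoich'")
    reaction(id = r$id,
             stoich = r$stoich,
             enzyme = r$enzyme,
             reversible = isTRUE(r$reversible),
             tags = as.character(unlist(r$tags)))
  })
  reaction_network(doc$name, mets, rxns)
}

#' Write a network to its JSON file
#'
#' Coefficients are written as integer or `"num/den"` strings, so a
#' save/load round trip preserves rational coefficients exactly.
#'
#' @param net a [reaction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  mets <- lapply(net$metabolites, function(m) {
    out <- list(id = m$id, name = m$name, role = m$role)
    if (!is.null(m$formula)) out$formula <- format(m$formula)
    out
  })
  rxns <- lapply(net$reactions, function(r) {
    co <- as.character(r$stoich)
    st <- as.list(co)
    names(st) <- reaction_met_ids(r)
    out <- list(id = r$id)
    if (!is.null(r$enzyme)) out$enzyme <- r$enzyme
    out$stoich <- st
    out$reversible <- r$reversible
    out$tags <- as.list(r$tags)
    out
  })
  doc <- list(name = net$name, metabolites = unname(mets), reactions = unname(rxns))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
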