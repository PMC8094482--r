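#' Minimum-substrate yield optimization
#'
#' Solves for the minimum moles of substrate per mole of product over a
#' reaction network at steady state (S v = 0 on every internal metabolite),
#' with irreversible reactions bounded at zero and the product flux fixed.
#' Cofactors are balanced strictly by default: a strict cofactor has no free
#' sink, so a network that cannot reoxidize NADPH it is forced to produce is
#' infeasible - the modelling expression of a redox-intolerant strain.
#'
#' @name yield_optimizer
NULL

#' Product sink reaction from precursor demand
#'
#' Builds the lumped synthesis reaction consuming a TAG's precursor demand
#' (acetyl-CoA, NADPH, glycerol-C3 backbone, plus carboxylation ATP) and
#' producing one product molecule, so networks automatically follow any
#' change of target TAG.
#'
#' @param tag a [tag_spec()] or TAG string.
#' @param met_ids named character vector mapping the roles `acetyl_coa`,
#'   `nadph`, `atp`, `glycerol_c3` and `product` to metabolite ids.
#' @param include_atp include the 1-ATP-per-malonyl-CoA carboxylation cost.
#' @param include_desaturation include desaturation cofactor in the NADPH
#'   coefficient.
#' @return a [reaction()] with id `"TAGSYN"`.
#' @export
tag_sink_reaction <- function(tag,
                              met_ids = c(acetyl_coa = "accoa", nadph = "nadph",
                                          atp = "atp", glycerol_c3 = "gly3p",
                                          product = "tag"),
                              include_atp = TRUE,
                              include_desaturation = FALSE) {
  d <- precursor_demand(tag, include_desaturation = include_desaturation)
  st <- list()
  st[[met_ids[["acetyl_coa"]]]] <- -d$acetyl_coa
  st[[met_ids[["nadph"]]]] <- -d$nadph_total
  if (include_atp) st[[met_ids[["atp"]]]] <- -d$atp_carboxylation
  st[[met_ids[["glycerol_c3"]]]] <- -d$glycerol_backbone_c3
  st[[met_ids[["product"]]]] <- 1
  reaction("TAGSYN", st, enzyme = "FAS", tags = c("lumped", "sink"))
}

#' Define a yield problem
#'
#' @param network a [reaction_network()].
#' @param substrate id of the exchange metabolite taken up (minimized).
#' @param product id of the exchange metabolite whose production is fixed.
#' @param product_amount moles of product per basis (rational or integer).
#' @param cofactor_policy named character vector over cofactor metabolite
#'   ids, values `"strict"` (exact zero net production) or `"overflow"`
#'   (free sink allowed). Cofactors not named default to `"strict"`.
#' @param atp_policy `"balanced_with_respiration"` (ATP balanced; NADH is
#'   reoxidized by the network's lumped respiration reaction) or
#'   `"ignored"` (ATP row is relaxed entirely).
#' @param atp_per_nadh ATP formed per NADH respired (effective P/O ratio)
#'   applied to reactions tagged `"respiration"`; rational, `"num/den"`
#'   string, or numeric integer. The default 16/15 reproduces the published
#'   whole-pathway accounting (see the methods vignette).
#' @return object of class `yield_problem`.
#' @export
yield_problem <- function(network, substrate = "glc", product = "tag",
                          product_amount = 1,
                          cofactor_policy = c(nadph = "strict", nadh = "strict"),
                          atp_policy = c("balanced_with_respiration", "ignored"),
                          atp_per_nadh = rq(16, 15)) {
  stopifnot(inherits(network, "reaction_network"))
  atp_policy <- match.arg(atp_policy)
  roles <- met_roles(network)
  for (who in c(substrate, product)) {
    if (!who %in% names(roles)) stop("no such metabolite: ", who)
    if (roles[[who]] != "exchange")
      stop(who, " must be an exchange metabolite")
  }
  pa <- if (is.rq(product_amount)) product_amount else rq_parse(product_amount)
  if (pa < 0) stop("product_amount must be >= 0")
  bad <- setdiff(cofactor_policy, c("strict", "overflow"))
  if (length(bad)) stop("unknown cofactor policy: ", paste(bad, collapse = ", "))
  structure(list(network = network, substrate = substrate, product = product,
                 product_amount = pa, cofactor_policy = cofactor_policy,
                 atp_policy = atp_policy,
                 atp_per_nadh = if (is.rq(atp_per_nadh)) atp_per_nadh
                                else rq_parse(atp_per_nadh)),
            class = "yield_problem")
}

# apply the problem's respiration stoichiometry to the network copy
apply_respiration <- function(net, atp_per_nadh) {
  for (i in seq_along(net$reactions)) {
    r <- net$reactions[[i]]
    if ("respiration" %in% r$tags && "atp" %in% reaction_met_ids(r)) {
      k <- match("atp", reaction_met_ids(r))
      r$stoich[k] <- atp_per_nadh
      net$reactions[[i]] <- r
    }
  }
  net
}

# assemble the standard-form LP for a yield problem
# columns: reactions (lexicographic by id; reversible split into __rev),
# then uptake, exports, cofactor overflow sinks, ATP relaxation columns
build_yield_lp <- function(problem, extra_slack_cofactors = character()) {
  net <- apply_respiration(problem$network, problem$atp_per_nadh)
  S <- stoichiometric_matrix(net)
  mids <- rownames(S$n)
  roles <- met_roles(net)
  ord <- order(colnames(S$n), method = "radix")
  cols <- list(); labels <- character(); kinds <- character()
  for (j in ord) {
    rid <- colnames(S$n)[j]
    cols[[length(cols) + 1L]] <- S[, j, drop = TRUE]
    labels <- c(labels, rid); kinds <- c(kinds, "fwd")
    if (net$reactions[[rid]]$reversible) {
      cols[[length(cols) + 1L]] <- rq(0) - S[, j, drop = TRUE]
      labels <- c(labels, paste0(rid, "__rev")); kinds <- c(kinds, "rev")
    }
  }
  unit_col <- function(id, sign) {
    v <- rq_zeros(length(mids))
    v[match(id, mids)] <- rq(sign)
    v
  }
  # substrate uptake (the objective)
  cols[[length(cols) + 1L]] <- unit_col(problem$substrate, 1)
  labels <- c(labels, "UPTAKE"); kinds <- c(kinds, "uptake")
  # free export for remaining exchange metabolites
  for (id in mids[roles == "exchange"]) {
    if (id %in% c(problem$substrate, problem$product)) next
    cols[[length(cols) + 1L]] <- unit_col(id, -1)
    labels <- c(labels, paste0("EX_", id)); kinds <- c(kinds, "export")
  }
  # cofactor overflow sinks
  pol <- problem$cofactor_policy
  for (id in mids[roles == "cofactor_pair_member"]) {
    mode <- if (id %in% names(pol)) pol[[id]] else "strict"
    if (mode == "overflow" || id %in% extra_slack_cofactors) {
      cols[[length(cols) + 1L]] <- unit_col(id, -1)
      labels <- c(labels, paste0("SLACK_", id)); kinds <- c(kinds, "slack")
    }
  }
  if (problem$atp_policy == "ignored" && "atp" %in% mids) {
    cols[[length(cols) + 1L]] <- unit_col("atp", 1)
    labels <- c(labels, "ATP_FREE_SOURCE"); kinds <- c(kinds, "relax")
    if (!"SLACK_atp" %in% labels) {
      cols[[length(cols) + 1L]] <- unit_col("atp", -1)
      labels <- c(labels, "ATP_FREE_SINK"); kinds <- c(kinds, "relax")
    }
  }
  A <- rq_zeros(length(mids), length(cols))
  for (j in seq_along(cols)) A[, j] <- cols[[j]]
  dimnames(A$n) <- list(mids, labels)
  b <- rq_zeros(length(mids))
  b[match(problem$product, mids)] <- problem$product_amount
  obj <- rq_zeros(length(cols))
  obj[match("UPTAKE", labels)] <- rq(1)
  list(A = A, b = b, obj = obj, labels = labels, kinds = kinds, net = net)
}

# map an LP solution vector back to per-reaction net fluxes (rq, named)
lp_fluxes <- function(lp, x) {
  rids <- names(lp$net$reactions)
  flux <- rq_zeros(length(rids))
  names(flux$n) <- rids; names(flux$d) <- rids
  for (rid in rids) {
    f <- x[match(rid, lp$labels)]
    rev_lab <- paste0(rid, "__rev")
    if (rev_lab %in% lp$labels) f <- f - x[match(rev_lab, lp$labels)]
    flux[match(rid, rids)] <- f
  }
  flux
}

#' Minimum substrate per unit product
#'
#' Minimizes substrate uptake subject to exact steady state on every
#' non-exchange metabolite, irreversibility bounds and a fixed product flux,
#' using the exact rational simplex. When the problem is infeasible the
#' returned solution carries a per-cofactor diagnosis naming the cofactor(s)
#' whose overproduction cannot be avoided.
#'
#' @param problem a [yield_problem()].
#' @return object of class `yield_solution`: `status`, exact `flux` (named),
#'   `substrate_per_product` (exact rational and numeric), `mass_yield_g_per_g`
#'   (when both metabolites carry formulas), `active_routes`, and for
#'   infeasible problems a `cofactor_diagnosis` data.frame.
#' @examples
#' net <- native_network()
#' min_substrate(yield_problem(net)) # 18 glucose per triolein
#' @export
min_substrate <- function(problem) {
  stopifnot(inherits(problem, "yield_problem"))
  lp <- build_yield_lp(problem)
  if (problem$product_amount == 0) {
    flux <- rq_zeros(length(lp$net$reactions))
    names(flux$n) <- names(lp$net$reactions)
    names(flux$d) <- names(lp$net$reactions)
    return(new_yield_solution(problem, "optimal", flux, rq(0), lp))
  }
  sol <- solve_lp_exact(lp$A, lp$b, lp$obj)
  if (sol$status == "unbounded") {
    on_ray <- lp$labels[which(as.numeric(sol$ray) != 0)]
    stop("yield LP is unbounded; free cycle through: ",
         paste(on_ray, collapse = ", "))
  }
  if (sol$status == "infeasible") {
    diag <- cofactor_diagnosis(problem)
    out <- new_yield_solution(problem, "infeasible", NULL, NULL, lp)
    out$cofactor_diagnosis <- diag
    return(out)
  }
  # exact post-verification of steady state
  resid <- rq_matvec(lp$A, sol$x) - lp$b
  if (any(resid$n != 0)) stop("internal error: nonzero steady-state residual")
  flux <- lp_fluxes(lp, sol$x)
  new_yield_solution(problem, "optimal", flux, sol$value, lp)
}

new_yield_solution <- function(problem, status, flux, uptake, lp) {
  out <- list(status = status, problem = problem)
  if (status == "optimal") {
    out$flux <- flux
    spp <- if (problem$product_amount > 0) uptake / problem$product_amount else rq(0)
    out$substrate_per_product <- spp
    net <- problem$network
    fs <- net$metabolites[[problem$substrate]]$formula
    fp <- net$metabolites[[problem$product]]$formula
    if (!is.null(fs) && !is.null(fp) && as.numeric(spp) > 0) {
      out$mass_yield_g_per_g <- mass_yield(spp, fs, 1, fp)
    }
    nz <- which(flux$n != 0)
    out$active_routes <- sort(names(flux$n)[nz])
  }
  structure(out, class = "yield_solution")
}

#' @export
print.yield_solution <- function(x, ...) {
  cat("<yield solution> status:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  ", as.character(x$substrate_per_product), " mol ", x$problem$substrate,
        " per mol ", x$problem$product,
        " (= ", round(as.numeric(x$substrate_per_product), 4), ")\n", sep = "")
    if (!is.null(x$mass_yield_g_per_g))
      cat("  mass yield: ", round(x$mass_yield_g_per_g, 4), " g/g\n", sep = "")
    cat("  active routes:", paste(x$active_routes, collapse = ", "), "\n")
  } else if (!is.null(x$cofactor_diagnosis)) {
    blk <- x$cofactor_diagnosis$cofactor[x$cofactor_diagnosis$blocking]
    cat("  blocking cofactor(s):", paste(blk, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Maximum mass yield (g product per g substrate)
#'
#' Mass-converts the [min_substrate()] optimum.
#'
#' @param problem a [yield_problem()].
#' @param digits optional rounding for reporting; `NULL` returns full
#'   precision.
#' @return g/g yield (numeric), or `NA` if the problem is infeasible.
#' @examples
#' round(max_mass_yield(yield_problem(native_network())), 2) # 0.27
#' @export
max_mass_yield <- function(problem, digits = NULL) {
  sol <- min_substrate(problem)
  if (sol$status != "optimal") return(NA_real_)
  y <- sol$mass_yield_g_per_g
  if (is.null(y)) stop("substrate or product has no molecular formula")
  if (is.null(digits)) y else round(y, digits)
}

# per-cofactor minimum unavoidable overproduction (auxiliary LPs)
cofactor_diagnosis <- function(problem) {
  roles <- met_roles(problem$network)
  cofs <- names(roles)[roles == "cofactor_pair_member"]
  pol <- problem$cofactor_policy
  strict <- cofs[vapply(cofs, function(id) {
    mode <- if (id %in% names(pol)) pol[[id]] else "strict"
    mode == "strict" && !(id == "atp" && problem$atp_policy == "ignored")
  }, logical(1))]
  lp <- build_yield_lp(problem, extra_slack_cofactors = strict)
  rows <- lapply(strict, function(id) {
    lab <- paste0("SLACK_", id)
    obj <- rq_zeros(ncol(lp$A$n))
    obj[match(lab, lp$labels)] <- rq(1)
    sol <- solve_lp_exact(lp$A, lp$b, obj)
    if (sol$status != "optimal") {
      return(data.frame(cofactor = id, min_overproduction = NA_real_,
                        exact = NA_character_, blocking = NA))
    }
    v <- sol$value
    data.frame(cofactor = id, min_overproduction = as.numeric(v),
               exact = as.character(v), blocking = as.numeric(v) > 0)
  })
  do.call(rbind, rows)
}

#' Feasibility and cofactor-balance report
#'
#' Always returns a report. For infeasible problems the report gives, for
#' each strictly balanced cofactor, the minimum overproduction per unit
#' product that no flux distribution can avoid (an auxiliary LP in which
#' every strict cofactor receives a slack sink); cofactors with a strictly
#' positive minimum are the blocking ones.
#'
#' @param problem a [yield_problem()].
#' @return object of class `feasibility_report` with fields `status`
#'   (`"feasible"`/`"infeasible"`) and `cofactors` (data.frame).
#' @examples
#' feasibility_report(yield_problem(dpfk_network()))
#' @export
feasibility_report <- function(problem) {
  lp <- build_yield_lp(problem)
  sol <- solve_lp_exact(lp$A, lp$b, lp$obj)
  status <- if (sol$status == "optimal") "feasible" else "infeasible"
  structure(list(status = status, cofactors = cofactor_diagnosis(problem)),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("<feasibility report> status:", x$status, "\n")
  print(x$cofactors, row.names = FALSE)
  invisible(x)
}

#' Brute-force yield oracle
#'
#' Independent verification of [min_substrate()] by exhaustive enumeration
#' of the basic feasible solutions of the steady-state polytope. Refuses
#' networks larger than the size guard.
#'
#' @param net a small [reaction_network()] (at most `max_reactions`).
#' @param substrate,product,product_amount,cofactor_policy,atp_policy,atp_per_nadh
#'   as in [yield_problem()].
#' @param max_reactions size guard on the reaction count.
#' @return list with `status` and, when optimal, exact
#'   `substrate_per_product` plus `bases_checked`.
#' @export
brute_force_yield_oracle <- function(net, substrate = "glc", product = "tag",
                                     product_amount = 1,
                                     cofactor_policy = c(nadph = "strict", nadh = "strict"),
                                     atp_policy = "balanced_with_respiration",
                                     atp_per_nadh = rq(16, 15),
                                     max_reactions = 14) {
  if (length(net$reactions) > max_reactions)
    stop("oracle refuses networks with more than ", max_reactions, " reactions")
  problem <- yield_problem(net, substrate, product, product_amount,
                           cofactor_policy, atp_policy, atp_per_nadh)
  lp <- build_yield_lp(problem)
  res <- enumerate_lp_exact(lp$A, lp$b, lp$obj)
  if (res$status != "optimal") return(list(status = res$status))
  list(status = "optimal",
       substrate_per_product = res$value / problem$product_amount,
       bases_checked = res$bases_checked)
}

#' Restrict a network to the active route of a solution
#'
#' Keeps only reactions carrying nonzero flux in `solution` (plus every
#' metabolite they reference). Useful to bring a fixture inside the
#' enumeration oracle's size guard.
#'
#' @param net a [reaction_network()].
#' @param solution an optimal [min_substrate()] solution on `net`.
#' @return a smaller [reaction_network()].
#' @export
reduce_to_active <- function(net, solution) {
  stopifnot(inherits(solution, "yield_solution"),
            solution$status == "optimal")
  keep <- names(solution$flux$n)[solution$flux$n != 0]
  rxns <- net$reactions[keep]
  used <- unique(unlist(lapply(rxns, reaction_met_ids)))
  mets <- net$metabolites[intersect(met_ids(net), used)]
  reaction_network(paste0(net$name, " (active route)"), unname(mets), unname(rxns))
}
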