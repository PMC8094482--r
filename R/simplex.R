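#' Exact rational linear programming
#'
#' Small dense two-phase primal simplex over exact rationals, plus a
#' brute-force basic-feasible-solution enumerator used as an independent
#' verification oracle. Both solve
#'   min c'x  s.t.  A x = b,  x >= 0
#' Bland's smallest-index rule is used for entering and leaving variables,
#' which both prevents cycling and makes the reported vertex deterministic
#' (columns are ordered by reaction id upstream).
#'
#' @name exact_lp
#' @keywords internal
NULL

# reduced cost row for basis `basis` under costs `cvec`:
# r_j = c_j - sum_i c_B(i) * T[i, j]
reduced_costs <- function(Tb, basis, cvec, ncols) {
  r <- rq_zeros(ncols)
  cb <- cvec[basis]
  for (j in seq_len(ncols)) {
    r[j] <- cvec[j] - rq_sum(cb * Tb[, j, drop = TRUE])
  }
  r
}

pivot_tableau <- function(Tb, r, s) {
  piv <- Tb[r, s]
  Tb[r, ] <- Tb[r, , drop = TRUE] / piv
  m <- nrow(Tb$n)
  for (i in seq_len(m)) {
    if (i == r) next
    f <- Tb[i, s]
    if (f$n != 0) Tb[i, ] <- Tb[i, , drop = TRUE] - f * Tb[r, , drop = TRUE]
  }
  Tb
}

# one simplex phase; `allowed` are columns permitted to enter
simplex_phase <- function(Tb, basis, cvec, allowed, rhs_col) {
  ncols <- rhs_col - 1L
  repeat {
    rc <- reduced_costs(Tb, basis, cvec, ncols)
    ent <- 0L
    for (j in allowed) {            # Bland: smallest eligible index enters
      if (rc[j] < 0) { ent <- j; break }
    }
    if (ent == 0L) return(list(Tb = Tb, basis = basis, status = "optimal"))
    # ratio test, Bland tie-break on basis variable index
    leave <- 0L; best <- NULL
    for (i in seq_len(nrow(Tb$n))) {
      a <- Tb[i, ent]
      if (a > 0) {
        ratio <- Tb[i, rhs_col] / a
        if (is.null(best) || ratio < best ||
            (ratio == best && basis[i] < basis[leave])) {
          best <- ratio; leave <- i
        }
      }
    }
    if (leave == 0L) {
      # unbounded: build the improving ray
      ray <- rq_zeros(ncols)
      ray[ent] <- rq(1)
      for (i in seq_len(nrow(Tb$n))) ray[basis[i]] <- rq(0) - Tb[i, ent]
      return(list(Tb = Tb, basis = basis, status = "unbounded",
                  ray = ray, entering = ent))
    }
    Tb <- pivot_tableau(Tb, leave, ent)
    basis[leave] <- ent
  }
}

#' Solve min c'x s.t. Ax = b, x >= 0 exactly
#'
#' @param A `rq` matrix (m x n).
#' @param b `rq` vector (m).
#' @param obj `rq` vector (n).
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   exact `x` and `value` when optimal, and `ray` when unbounded.
#' @keywords internal
solve_lp_exact <- function(A, b, obj) {
  if (!is.rq(A)) A <- rq(A)
  if (!is.rq(b)) b <- rq(b)
  if (!is.rq(obj)) obj <- rq(obj)
  m <- nrow(A$n); n <- ncol(A$n)
  stopifnot(length(b) == m, length(obj) == n)
  # orient rows so b >= 0
  for (i in seq_len(m)) {
    if (b[i] < 0) { b[i] <- rq(0) - b[i]; A[i, ] <- rq(0) - A[i, , drop = TRUE] }
  }
  # tableau [A | I | b], basis = artificials
  ncols <- n + m; rhs_col <- ncols + 1L
  Tb <- rq_zeros(m, rhs_col)
  Tb[, seq_len(n)] <- A
  for (i in seq_len(m)) Tb[i, n + i] <- rq(1)
  Tb[, rhs_col] <- b
  basis <- n + seq_len(m)

  c1 <- rq_c(rq(numeric(n)), rq(rep(1, m)))
  ph1 <- simplex_phase(Tb, basis, c1, seq_len(n), rhs_col)
  Tb <- ph1$Tb; basis <- ph1$basis
  ph1_val <- rq_sum(c1[basis] * Tb[, rhs_col, drop = TRUE])
  if (ph1_val > 0) return(list(status = "infeasible", phase1_excess = ph1_val))

  # drive remaining artificials out of the basis (or drop redundant rows)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      piv <- 0L
      for (j in seq_len(n)) if (Tb[i, j]$n != 0) { piv <- j; break }
      if (piv == 0L) keep[i] <- FALSE else { Tb <- pivot_tableau(Tb, i, piv); basis[i] <- piv }
    }
  }
  if (!all(keep)) {
    Tb <- Tb[keep, , drop = FALSE]
    basis <- basis[keep]
  }

  c2 <- rq_c(obj, rq(numeric(m)))
  ph2 <- simplex_phase(Tb, basis, c2, seq_len(n), rhs_col)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", ray = ph2$ray[seq_len(n)]))
  }
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- rq_zeros(n)
  for (i in seq_along(basis)) if (basis[i] <= n) x[basis[i]] <- Tb[i, rhs_col]
  list(status = "optimal", x = x, value = rq_sum(obj * x), basis = sort(basis))
}

# exact forward elimination; returns indices of an independent, consistent
# subset of rows, or signals inconsistency
independent_rows <- function(A, b) {
  m <- nrow(A$n); n <- ncol(A$n)
  pivots <- list()   # list of (row rq vector length n+1)
  kept <- integer()
  for (i in seq_len(m)) {
    row <- rq_c(A[i, , drop = TRUE], b[i])
    for (p in pivots) {
      lead <- p$col
      if (row[lead]$n != 0) row <- row - (row[lead] / p$row[lead]) * p$row
    }
    nz <- which(row$n[seq_len(n)] != 0)
    if (!length(nz)) {
      if (row[n + 1L]$n != 0) return(list(inconsistent = TRUE))
      next
    }
    pivots[[length(pivots) + 1L]] <- list(row = row, col = nz[1])
    kept <- c(kept, i)
  }
  list(inconsistent = FALSE, rows = kept)
}

# solve square exact system Bx = rhs; NULL if singular
rq_solve_square <- function(B, rhs) {
  k <- nrow(B$n)
  M <- rq_zeros(k, k + 1L)
  M[, seq_len(k)] <- B
  M[, k + 1L] <- rhs
  for (col in seq_len(k)) {
    piv <- 0L
    for (i in col:k) if (M[i, col]$n != 0) { piv <- i; break }
    if (piv == 0L) return(NULL)
    if (piv != col) {
      tmp <- M[col, , drop = TRUE]; M[col, ] <- M[piv, , drop = TRUE]; M[piv, ] <- tmp
    }
    M[col, ] <- M[col, , drop = TRUE] / M[col, col]
    for (i in seq_len(k)) {
      if (i == col) next
      f <- M[i, col]
      if (f$n != 0) M[i, ] <- M[i, , drop = TRUE] - f * M[col, , drop = TRUE]
    }
  }
  M[, k + 1L]
}

#' Enumerate basic feasible solutions of Ax = b, x >= 0
#'
#' Independent brute-force oracle: after removing redundant rows, every
#' basis (column subset of size rank(A)) is solved exactly; the feasible
#' one with minimal objective is returned. Refuses problems beyond the
#' size guard.
#'
#' @inheritParams solve_lp_exact
#' @param max_bases refuse if the number of bases exceeds this.
#' @return list with `status`, `x`, `value`, `bases_checked`.
#' @keywords internal
enumerate_lp_exact <- function(A, b, obj, max_bases = 50000) {
  if (!is.rq(A)) A <- rq(A)
  if (!is.rq(b)) b <- rq(b)
  if (!is.rq(obj)) obj <- rq(obj)
  ir <- independent_rows(A, b)
  if (isTRUE(ir$inconsistent)) return(list(status = "infeasible"))
  A <- A[ir$rows, , drop = FALSE]
  b2 <- b[ir$rows]
  r <- nrow(A$n); n <- ncol(A$n)
  if (r == 0L) {
    return(list(status = "optimal", x = rq_zeros(n), value = rq(0), bases_checked = 0L))
  }
  if (n < r) return(list(status = "infeasible"))
  if (choose(n, r) > max_bases)
    stop("basis enumeration refused: ", choose(n, r),
         " bases exceeds the size guard (", max_bases, ")")
  combos <- utils::combn(n, r)
  best <- NULL; best_x <- NULL; checked <- 0L
  for (k in seq_len(ncol(combos))) {
    J <- combos[, k]
    xj <- rq_solve_square(A[, J, drop = FALSE], b2)
    if (is.null(xj)) next
    checked <- checked + 1L
    if (any(rq_cmp(xj, rq(0), "<"))) next
    val <- rq_sum(obj[J] * xj)
    if (is.null(best) || val < best) {
      best <- val
      best_x <- rq_zeros(n)
      best_x[J] <- xj
    }
  }
  if (is.null(best)) return(list(status = "infeasible", bases_checked = checked))
  list(status = "optimal", x = best_x, value = best, bases_checked = checked)
}
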