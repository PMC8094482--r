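#' Exact rational numbers
#'
#' Internal vectorised rational arithmetic used by the stoichiometric matrix
#' and the exact simplex. Values are stored as reduced integer numerator /
#' denominator pairs held in doubles; magnitudes are guarded well below 2^53
#' so every operation is exact.
#'
#' @param n numerator(s), integer-valued.
#' @param d denominator(s), integer-valued, nonzero.
#' @return an object of class `rq` with fields `n` and `d` (same shape).
#' @keywords internal
#' @noRd
rq <- function(n, d = 1) {
  if (is.rq(n)) {
    if (!all(d == 1)) stop("cannot combine an rq numerator with a denominator")
    return(n)
  }
  if (!is.numeric(n) || !is.numeric(d)) stop("rq() needs numeric input")
  if (any(n != round(n)) || any(d != round(d)))
    stop("rq() components must be integer-valued")
  if (any(d == 0)) stop("zero denominator")
  if (length(d) == 1L && length(n) > 1L) d <- rep(d, length.out = length(n))
  dd <- dim(n)
  out <- rq_reduce(as.numeric(n), as.numeric(d))
  if (!is.null(dd)) { dim(out$n) <- dd; dim(out$d) <- dd }
  structure(list(n = out$n, d = out$d), class = "rq")
}

is.rq <- function(x) inherits(x, "rq")

# elementwise gcd of non-negative integer-valued doubles
gcd_vec <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(b > 0, b, a)
    b <- r
  }
  a
}

RQ_GUARD <- 2^51

rq_reduce <- function(n, d) {
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- gcd_vec(n, d)
  g[g == 0] <- 1
  n <- n / g; d <- d / g
  d[n == 0] <- 1
  if (any(abs(n) > RQ_GUARD) || any(d > RQ_GUARD))
    stop("exact rational overflow guard tripped")
  list(n = n, d = d)
}

rq_bin <- function(e1, e2, op) {
  if (!is.rq(e1)) e1 <- rq(e1)
  if (!is.rq(e2)) e2 <- rq(e2)
  dd <- if (!is.null(dim(e1$n))) dim(e1$n) else dim(e2$n)
  n1 <- e1$n; d1 <- e1$d; n2 <- e2$n; d2 <- e2$d
  res <- switch(op,
    "+" = list(n = n1 * d2 + n2 * d1, d = d1 * d2),
    "-" = list(n = n1 * d2 - n2 * d1, d = d1 * d2),
    "*" = list(n = n1 * n2, d = d1 * d2),
    "/" = {
      if (any(n2 == 0)) stop("rational division by zero")
      list(n = n1 * d2, d = d1 * n2)
    },
    stop("unsupported rq op: ", op)
  )
  out <- rq_reduce(res$n, res$d)
  if (!is.null(dd)) { dim(out$n) <- dd; dim(out$d) <- dd }
  structure(list(n = out$n, d = out$d), class = "rq")
}

rq_cmp <- function(e1, e2, op) {
  if (!is.rq(e1)) e1 <- rq(e1)
  if (!is.rq(e2)) e2 <- rq(e2)
  lhs <- e1$n * e2$d
  rhs <- e2$n * e1$d
  switch(op,
    "==" = lhs == rhs, "!=" = lhs != rhs,
    "<"  = lhs < rhs,  "<=" = lhs <= rhs,
    ">"  = lhs > rhs,  ">=" = lhs >= rhs,
    stop("unsupported comparison")
  )
}

#' @export
Ops.rq <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rq_bin(rq(0), e1, "-"))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rq")
  }
  if (.Generic %in% c("+", "-", "*", "/")) return(rq_bin(e1, e2, .Generic))
  if (.Generic %in% c("==", "!=", "<", "<=", ">", ">=")) return(rq_cmp(e1, e2, .Generic))
  stop(.Generic, " not defined for rq")
}

#' @export
length.rq <- function(x) length(x$n)

#' @export
dim.rq <- function(x) dim(x$n)

#' @export
`dim<-.rq` <- function(x, value) { dim(x$n) <- value; dim(x$d) <- value; x }

#' @export
`[.rq` <- function(x, i, j, ..., drop = TRUE) {
  if (missing(j) && is.null(dim(x$n))) {
    structure(list(n = x$n[i], d = x$d[i]), class = "rq")
  } else if (missing(j)) {
    structure(list(n = x$n[i, , drop = drop], d = x$d[i, , drop = drop]), class = "rq")
  } else if (missing(i)) {
    structure(list(n = x$n[, j, drop = drop], d = x$d[, j, drop = drop]), class = "rq")
  } else {
    structure(list(n = x$n[i, j, drop = drop], d = x$d[i, j, drop = drop]), class = "rq")
  }
}

#' @export
`[<-.rq` <- function(x, i, j, ..., value) {
  if (!is.rq(value)) value <- rq(value)
  if (missing(j) && is.null(dim(x$n))) {
    x$n[i] <- value$n; x$d[i] <- value$d
  } else if (missing(j)) {
    x$n[i, ] <- value$n; x$d[i, ] <- value$d
  } else if (missing(i)) {
    x$n[, j] <- value$n; x$d[, j] <- value$d
  } else {
    x$n[i, j] <- value$n; x$d[i, j] <- value$d
  }
  x
}

#' @export
t.rq <- function(x) structure(list(n = t(x$n), d = t(x$d)), class = "rq")

#' @export
as.numeric.rq <- function(x, ...) {
  out <- x$n / x$d
  attributes(out) <- attributes(x$n)
  out
}

#' @export
as.double.rq <- function(x, ...) as.numeric.rq(x)

#' @export
as.character.rq <- function(x, ...) {
  out <- ifelse(x$d == 1, format_plain(x$n), paste0(format_plain(x$n), "/", format_plain(x$d)))
  attributes(out) <- attributes(x$n)
  out
}

format_plain <- function(v) format(v, scientific = FALSE, trim = TRUE)

#' @export
format.rq <- function(x, ...) as.character(x)

#' @export
print.rq <- function(x, ...) {
  cat("<exact rational>\n")
  print(as.character(x), quote = FALSE)
  invisible(x)
}

rq_c <- function(...) {
  parts <- lapply(list(...), function(p) if (is.rq(p)) p else rq(p))
  structure(list(
    n = unlist(lapply(parts, function(p) as.vector(p$n))),
    d = unlist(lapply(parts, function(p) as.vector(p$d)))
  ), class = "rq")
}

rq_sum <- function(x) {
  acc <- rq(0)
  for (k in seq_len(length(x))) acc <- acc + x[k]
  acc
}

rq_rep <- function(x, times) {
  structure(list(n = rep(x$n, times), d = rep(x$d, times)), class = "rq")
}

rq_zeros <- function(nrow, ncol = NULL) {
  if (is.null(ncol)) rq(numeric(nrow)) else rq(matrix(0, nrow, ncol))
}

# exact matrix %*% vector
rq_matvec <- function(A, v) {
  m <- nrow(A$n)
  out <- rq_zeros(m)
  for (i in seq_len(m)) out[i] <- rq_sum(A[i, , drop = TRUE] * v)
  out
}

# parse "a/b" or "a" strings (also plain integers) into rq
rq_parse <- function(s) {
  if (is.numeric(s)) return(rq(s))
  s <- as.character(s)
  bad <- !grepl("^\\s*-?[0-9]+\\s*(/\\s*-?[0-9]+\\s*)?$", s)
  if (any(bad)) stop("malformed rational literal: ", paste(s[bad], collapse = ", "))
  parts <- strsplit(s, "/", fixed = TRUE)
  n <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  d <- vapply(parts, function(p) if (length(p) > 1L) as.numeric(p[2]) else 1, numeric(1))
  rq(n, d)
}
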