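#' Molecular formulas
#'
#' A molecular formula is a named vector of non-negative integer element
#' counts, e.g. `C6H12O6`. Formulas are used for molar-mass conversion of
#' molar yields to mass yields and for elemental balance checks of network
#' reactions. Only a small vocabulary of biochemical elements is recognised.
#'
#' @name mol_formula
NULL

# IUPAC 2021 conventional atomic weights, two-decimal working precision
ATOMIC_WEIGHTS <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974, S = 32.06,
  Na = 22.990, K = 39.098, Mg = 24.305, Fe = 55.845, Cl = 35.45
)

#' Construct a molecular formula
#'
#' @param counts named numeric vector of element counts, or a formula string
#'   such as `"C6H12O6"` (element symbols with optional counts).
#' @return object of class `mol_formula`: a named integer vector of counts.
#' @examples
#' mol_formula("C57H104O6")
#' mol_formula(c(C = 6, H = 12, O = 6))
#' @export
mol_formula <- function(counts) {
  if (is.character(counts)) counts <- parse_formula_string(counts)
  if (inherits(counts, "mol_formula")) return(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("element counts must be named")
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown))
    stop("unrecognized element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("a molecular formula needs at least one atom")
  structure(as.integer(round(counts)), names = names(counts), class = "mol_formula")
}

parse_formula_string <- function(s) {
  stopifnot(length(s) == 1L, is.character(s))
  s <- trimws(s)
  if (!nzchar(s)) stop("a molecular formula needs at least one atom")
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s)) stop("malformed formula string: ", s)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  counts <- tapply(ct, el, sum)
  out <- as.numeric(counts); names(out) <- names(counts)
  out
}

#' @export
format.mol_formula <- function(x, ...) {
  # Hill order: C, H, then remaining elements alphabetically
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(x[ord] == 1, "", x[ord]), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula>", format(x), " (", round(molar_mass(x), 3), " g/mol)\n", sep = "")
  invisible(x)
}

#' Molar mass of a molecular formula
#'
#' Sum of conventional atomic weights times element counts.
#'
#' @param f a `mol_formula`, a formula string, or a named count vector.
#' @return molar mass in g/mol.
#' @examples
#' molar_mass("C6H12O6") # 180.156
#' @export
molar_mass <- function(f) {
  f <- mol_formula(f)
  sum(ATOMIC_WEIGHTS[names(f)] * as.numeric(f))
}

# element count (0 if absent)
formula_count <- function(f, element) {
  if (element %in% names(f)) as.numeric(f[[element]]) else 0
}
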