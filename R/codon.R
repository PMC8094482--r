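#' Rare-codon profiling and replacement
#'
#' Implements the gene-design rule used to raise heterologous expression:
#' every codon whose relative synonymous usage is at or below a threshold
#' (2 % by default) is replaced by its highest-frequency synonymous codon,
#' leaving the encoded protein unchanged. Frequencies are per-amino-acid
#' fractions (each synonymous family sums to 1): a genome-wide per-codon
#' fraction would make a 2 % cut meaningless for one- and two-codon
#' families.
#'
#' @name codon_tools
NULL

standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  # DNA alphabet
  stats::setNames(as.character(gc), chartr("U", "T", names(gc)))
}

sense_codons <- function() {
  code <- standard_code()
  sort(names(code)[code != "*"])
}

#' Codon usage table
#'
#' @param x data.frame with columns `codon` (DNA triplet), `amino_acid`
#'   (one-letter), `fraction` (relative synonymous usage in `[0, 1]`).
#' @return object of class `codon_usage_table` (a data.frame sorted by
#'   amino acid then codon).
#' @details All 61 sense codons must be present, amino-acid assignments
#'   must follow the standard genetic code, and fractions within each
#'   synonymous family must sum to 1 (tolerance 1e-6). Stop codons are not
#'   part of the table and are never rewritten.
#' @export
codon_usage_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("codon", "amino_acid", "fraction")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("usage table missing column(s): ", paste(missing, collapse = ", "))
  x$codon <- toupper(chartr("U", "T", x$codon))
  code <- standard_code()
  bad <- setdiff(x$codon, names(code))
  if (length(bad)) stop("invalid codon(s): ", paste(bad, collapse = ", "))
  if (any(code[x$codon] == "*")) stop("stop codons do not belong in a usage table")
  wrong <- x$codon[x$amino_acid != code[x$codon]]
  if (length(wrong))
    stop("amino-acid assignment disagrees with the standard code for: ",
         paste(wrong, collapse = ", "))
  absent <- setdiff(sense_codons(), x$codon)
  if (length(absent))
    stop("usage table must cover all 61 sense codons; missing: ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(x$codon)) stop("duplicated codon rows")
  if (any(x$fraction < 0 | x$fraction > 1)) stop("fractions must lie in [0, 1]")
  sums <- tapply(x$fraction, x$amino_acid, sum)
  off <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(off))
    stop("synonymous-family fractions must sum to 1; off for: ",
         paste(off, collapse = ", "))
  out <- x[order(x$amino_acid, x$codon), need]
  rownames(out) <- NULL
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Read / write a codon usage TSV (columns codon, amino_acid, fraction)
#'
#' @param path file path.
#' @return a [codon_usage_table()].
#' @export
read_codon_table <- function(path) {
  codon_usage_table(utils::read.delim(path, colClasses = c(
    codon = "character", amino_acid = "character", fraction = "numeric")))
}

#' @rdname read_codon_table
#' @param table a [codon_usage_table()].
#' @export
write_codon_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic codon usage table
#'
#' Random but valid relative synonymous usage (normalized exponential
#' draws per family), for tests and examples; not the usage of any real
#' genome.
#'
#' @param seed integer seed.
#' @return a [codon_usage_table()].
#' @export
synthetic_usage_table <- function(seed = 1L) {
  code <- standard_code()
  sc <- sense_codons()
  aa <- code[sc]
  frac <- local_seed(seed, {
    u <- stats::rexp(length(sc))
    as.numeric(u / ave(u, aa, FUN = sum))
  })
  codon_usage_table(data.frame(codon = sc, amino_acid = unname(aa),
                               fraction = frac))
}

#' Coding sequence
#'
#' @param seq DNA string (A/C/G/T), length divisible by 3, no internal stop
#'   codons. A missing ATG start triggers a warning only.
#' @return object of class `coding_sequence` (validated character scalar).
#' @export
coding_sequence <- function(seq) {
  if (inherits(seq, "coding_sequence")) return(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("\\s", "", seq))
  if (grepl("[^ACGT]", seq)) stop("coding sequence may contain only A, C, G, T")
  if (nchar(seq) == 0L || nchar(seq) %% 3 != 0L)
    stop("coding sequence length must be a positive multiple of 3")
  cods <- split_codons(seq)
  code <- standard_code()
  stops <- which(code[cods] == "*")
  if (length(stops) && any(stops < length(cods)))
    stop("internal stop codon at codon position ",
         paste(stops[stops < length(cods)], collapse = ", "))
  if (cods[1] != "ATG") warning("coding sequence does not start with ATG")
  structure(seq, class = "coding_sequence")
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq) - 2, by = 3), seq(3, nchar(seq), by = 3))
}

#' Translate a coding sequence (standard code)
#'
#' @param cds a [coding_sequence()] or DNA string.
#' @return one-letter protein string (terminal stop omitted).
#' @export
translate_cds <- function(cds) {
  cds <- coding_sequence(cds)
  aa <- standard_code()[split_codons(unclass(cds))]
  paste(aa[aa != "*"], collapse = "")
}

# per-codon bookkeeping used by both profiling and replacement: the terminal
# stop codon (if present) is excluded; `best` is each family's
# maximum-frequency codon, ties broken by lexicographically smallest codon
codon_frame <- function(cds, table, threshold) {
  cds <- coding_sequence(cds)
  table <- codon_usage_table(table)
  cods <- split_codons(unclass(cds))
  code <- standard_code()
  n <- length(cods)
  has_stop <- code[cods[n]] == "*"
  idx <- seq_len(if (has_stop) n - 1L else n)
  hit <- match(cods[idx], table$codon)
  if (anyNA(hit)) stop("codon absent from usage table: ",
                       paste(unique(cods[idx][is.na(hit)]), collapse = ", "))
  # family maximum, deterministic tie-break
  ord <- order(table$amino_acid, -table$fraction, table$codon)
  tb <- table[ord, ]
  best <- tb[!duplicated(tb$amino_acid), ]
  best_of <- stats::setNames(best$codon, best$amino_acid)
  data.frame(position = idx,
             codon = cods[idx],
             fraction = table$fraction[hit],
             best = unname(best_of[table$amino_acid[hit]]),
             rare = table$fraction[hit] <= threshold,
             stringsAsFactors = FALSE)
}

#' Profile replaceable rare codons
#'
#' Positions (1-based codon index) of codons at or below the usage
#' threshold that are not already their family's maximum-frequency codon
#' (i.e. exactly the codons [replace_rare_codons()] would change).
#'
#' @param cds a [coding_sequence()] or DNA string.
#' @param table a [codon_usage_table()].
#' @param threshold inclusive usage cutoff (default 0.02).
#' @return list with `count`, `positions`, `codons`.
#' @export
rare_codon_profile <- function(cds, table, threshold = 0.02) {
  fr <- codon_frame(cds, table, threshold)
  sel <- fr$rare & fr$codon != fr$best
  list(count = sum(sel), positions = fr$position[sel], codons = fr$codon[sel])
}

#' Replace rare codons by their best synonymous codon
#'
#' Every codon with usage at or below `threshold` is replaced by the
#' maximum-frequency codon of its synonymous family (ties broken toward the
#' lexicographically smallest codon); the encoded protein is unchanged and
#' the operation is idempotent. Stop codons are never rewritten.
#'
#' @inheritParams rare_codon_profile
#' @return object of class `codon_optimization`: `sequence` (the new
#'   [coding_sequence()]) and `changes` (data.frame `position`, `old`,
#'   `new`).
#' @examples
#' tab <- synthetic_usage_table(7)
#' out <- replace_rare_codons("ATGGCTGCATAA", tab, threshold = 0.1)
#' @export
replace_rare_codons <- function(cds, table, threshold = 0.02) {
  cds <- coding_sequence(cds)
  fr <- codon_frame(cds, table, threshold)
  cods <- split_codons(unclass(cds))
  sel <- fr$rare & fr$codon != fr$best
  changes <- data.frame(position = fr$position[sel], old = fr$codon[sel],
                        new = fr$best[sel], stringsAsFactors = FALSE)
  cods[fr$position[sel]] <- fr$best[sel]
  out <- coding_sequence(paste(cods, collapse = ""))
  structure(list(sequence = out, changes = changes, threshold = threshold),
            class = "codon_optimization")
}

#' @export
print.codon_optimization <- function(x, ...) {
  cat("<codon optimization> ", nrow(x$changes), " substitution(s) at usage <= ",
      x$threshold, "\n", sep = "")
  if (nrow(x$changes)) print(utils::head(x$changes, 10), row.names = FALSE)
  invisible(x)
}

#' Read / write coding sequences as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O returning validated
#' [coding_sequence()] objects.
#'
#' @param path FASTA file.
#' @return named list of [coding_sequence()].
#' @export
read_fasta_cds <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(as.character(set), coding_sequence)
  stats::setNames(out, names(set))
}

#' @rdname read_fasta_cds
#' @param seqs named list (or single) of [coding_sequence()] objects.
#' @export
write_fasta_cds <- function(seqs, path) {
  if (inherits(seqs, "coding_sequence")) seqs <- list(cds = seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, unclass, character(1)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
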