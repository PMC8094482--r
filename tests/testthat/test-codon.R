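test_that("usage tables are validated against the standard code", {
  tab <- toy_usage_table()
  expect_s3_class(tab, "codon_usage_table")
  expect_equal(nrow(tab), 61)
  bad <- as.data.frame(tab); bad$fraction[bad$codon == "CTG"] <- 0.9
  expect_error(codon_usage_table(bad), "sum to 1")
  bad2 <- as.data.frame(tab)[-1, ]
  expect_error(codon_usage_table(bad2), "61 sense codons")
  bad3 <- as.data.frame(tab); bad3$amino_acid[bad3$codon == "ATG"] <- "K"
  expect_error(codon_usage_table(bad3), "disagrees")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_codon_table(tab, p)
  expect_equal(as.data.frame(read_codon_table(p)), as.data.frame(tab))
})

test_that("coding sequences are validated", {
  expect_error(coding_sequence("ATGCC"), "multiple of 3")
  expect_error(coding_sequence("ATGTAAGCT"), "internal stop")
  expect_error(coding_sequence("ATGNNNTAA"), "only A, C, G, T")
  expect_warning(coding_sequence("GCTGCT"), "ATG")
  expect_silent(coding_sequence("ATGGCTTAA"))
})

test_that("the toy table drives exactly the expected substitutions", {
  # codons 3 (TTA, leucine at 1%) and 4 (GGG, glycine at 2%) are rare;
  # their family maxima are CTG and GGC
  cds <- coding_sequence("ATGCTGTTAGGGGGTAAATAA")
  tab <- toy_usage_table()
  prof <- rare_codon_profile(cds, tab, threshold = 0.02)
  expect_equal(prof$count, 2L)
  expect_equal(prof$positions, c(3L, 4L))
  expect_equal(prof$codons, c("TTA", "GGG"))
  out <- replace_rare_codons(cds, tab, threshold = 0.02)
  expect_equal(unclass(out$sequence), "ATGCTGCTGGGCGGTAAATAA")
  expect_equal(out$changes$old, c("TTA", "GGG"))
  expect_equal(out$changes$new, c("CTG", "GGC"))
  # a sequence free of rare codons is untouched
  clean <- coding_sequence("ATGCTGGGCAAATAA")
  out2 <- replace_rare_codons(clean, tab, threshold = 0.02)
  expect_equal(unclass(out2$sequence), unclass(clean))
  expect_equal(nrow(out2$changes), 0L)
})

test_that("replacement preserves the protein and is idempotent", {
  tab <- synthetic_usage_table(5)
  set.seed(99)
  for (i in 1:200) {
    cds <- random_cds(sample(10:40, 1))
    out <- replace_rare_codons(cds, tab, threshold = 0.05)
    # independent translation oracle
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(unclass(out$sequence)))),
      as.character(Biostrings::translate(Biostrings::DNAString(unclass(cds)))))
    again <- replace_rare_codons(out$sequence, tab, threshold = 0.05)
    expect_identical(unclass(again$sequence), unclass(out$sequence))
    expect_equal(nrow(again$changes), 0L)
    # profile count equals the change-report length
    expect_equal(rare_codon_profile(cds, tab, threshold = 0.05)$count,
                 nrow(out$changes))
  }
})

test_that("the rare-codon count is monotone in the threshold", {
  tab <- synthetic_usage_table(8)
  set.seed(123)
  cds <- random_cds(60)
  counts <- vapply(c(0, 0.01, 0.02, 0.05, 0.2, 1),
                   function(th) rare_codon_profile(cds, tab, th)$count,
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  # threshold 0 flags nothing, threshold 1 flags everything replaceable:
  # every codon of a multi-codon family except the family maximum
  expect_equal(counts[1], 0L)
  fr <- oleoflux:::codon_frame(cds, tab, 1)
  expect_equal(counts[length(counts)], sum(fr$codon != fr$best))
})

test_that("stop codons are never rewritten and odd input errors", {
  tab <- toy_usage_table()
  out <- replace_rare_codons("ATGTTATAA", tab, threshold = 0.02)
  expect_equal(substring(unclass(out$sequence), 7, 9), "TAA")
  # FASTA round trip
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta_cds(list(gene = coding_sequence("ATGCTGTTATAA")), p)
  back <- read_fasta_cds(p)
  expect_equal(unclass(back$gene), "ATGCTGTTATAA")
})
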