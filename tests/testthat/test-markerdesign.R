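# deterministic amplicons: A-homopolymers with planted recognition sites
plant <- function(len, site, at) {
  # `at` is the 1-based position where the site starts
  paste0(strrep("A", at - 1), site, strrep("A", len - at + 1 - nchar(site)))
}

test_that("restriction-site search maps IUPAC matches to top-strand cuts", {
  ecori <- enzyme("EcoRI", "GAATTC", 1)
  expect_identical(find_sites("GGAATTCC", ecori), 2L)
  expect_identical(find_sites("AAAAAAAA", ecori), integer(0))
  # IUPAC ambiguity: W matches A
  expect_identical(find_sites("GGACC", enzyme("x", "GGWCC", 2)), 2L)
  expect_identical(find_sites("GGTCC", enzyme("x", "GGWCC", 2)), 2L)
  expect_identical(find_sites("GGCCC", enzyme("x", "GGWCC", 2)), integer(0))
  # reverse-strand recognition of a non-palindromic site (BsmAI GTCTC(1/5))
  bsmai <- enzyme("BsmAI", "GTCTC", 6)
  s <- plant(40, "GAGAC", 20)       # bottom-strand GTCTC
  expect_identical(find_sites(s, bsmai), (20L - 1L) + 5L - 6L)
  expect_error(enzyme("bad", "GAXTC", 1), class = "slafbsa_error_definition")
  expect_error(find_sites("ACGU", enzyme("AluI", "AGCT", 2)),
               class = "slafbsa_error_format")
})

test_that("site search is consistent under reverse complement", {
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  enzymes <- list(enzyme("AluI", "AGCT", 2),      # central palindromic cut
                  enzyme("BsmAI", "GTCTC", 6))    # non-palindromic type IIS
  withr::with_seed(8, {
    for (i in 1:20) {
      s <- random_dna(300)
      for (enz in enzymes) {
        fwd <- find_sites(s, enz)
        rc <- find_sites(revcomp(s), enz)
        expect_setequal(300L - rc, fwd)
      }
    }
  })
})

test_that("digest fragments partition the amplicon", {
  bsmai <- enzyme("BsmAI", "GTCTC", 6)
  blank <- strrep("A", 250)
  expect_identical(digest_fragments(blank, bsmai), 250L)
  # site placed so the top-strand cut falls at 196
  cut196 <- plant(250, "GTCTC", 191)
  expect_identical(find_sites(cut196, bsmai), 196L)
  expect_identical(digest_fragments(cut196, bsmai), c(196L, 54L))
  # cut at position 0 leaves the full-length fragment
  mluci <- enzyme("MluCI", "AATT", 0)
  expect_identical(digest_fragments(plant(30, "AATT", 1), mluci), 30L)

  # length conservation on random amplicon/enzyme pairs
  all_enz <- load_enzymes()
  withr::with_seed(9, {
    for (i in 1:100) {
      s <- random_dna(sample(80:300, 1))
      enz <- all_enz[[sample(length(all_enz), 1)]]
      fr <- digest_fragments(s, enz)
      expect_identical(sum(fr), nchar(s))
      expect_true(all(fr > 0))
    }
  })
})

test_that("diagnostic enzymes are ranked by gel resolvability", {
  bsmai <- enzyme("BsmAI", "GTCTC", 6)
  aluI <- enzyme("AluI", "AGCT", 2)
  allele_a <- strrep("A", 250)                  # no sites
  allele_b <- plant(250, "GTCTC", 191)          # BsmAI cut at 196

  none <- diagnostic_enzymes(allele_a, allele_a, list(bsmai, aluI))
  expect_identical(nrow(none), 0L)

  one <- diagnostic_enzymes(allele_a, allele_b, list(bsmai, aluI))
  expect_identical(one$enzyme, "BsmAI")
  expect_equal(one$min_band_diff, 54)
  # symmetric in allele order
  expect_equal(diagnostic_enzymes(allele_b, allele_a,
                                  list(bsmai, aluI))$min_band_diff, 54)

  # an enzyme with a larger minimum band difference ranks first
  allele_b2 <- plant(250, "AGCT", 124)          # AluI cut at 125
  allele_b2 <- paste0(substr(allele_b2, 1, 190), "GTCTC",
                      substr(allele_b2, 196, 250))
  ranked <- diagnostic_enzymes(allele_a, allele_b2, list(bsmai, aluI))
  expect_identical(ranked$enzyme, c("AluI", "BsmAI"))
  expect_true(all(diff(ranked$min_band_diff) <= 0))
})

test_that("InDel amplicon sizing measures the primer-bounded product", {
  withr::with_seed(10, template <- random_dna(200))
  fwd <- substr(template, 11, 30)
  rev_site <- substr(template, 171, 190)
  rev_primer <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev_site)))
  same <- indel_amplicon_sizes(template, template, fwd, rev_primer)
  expect_identical(same$size_a, 180L)
  expect_identical(same$delta, 0L)

  # 5-bp deletion between the primers
  delled <- paste0(substr(template, 1, 99), substr(template, 105, 200))
  del5 <- indel_amplicon_sizes(template, delled, fwd, rev_primer)
  expect_identical(del5$size_b, 175L)
  expect_identical(del5$delta, 5L)

  # deletion destroying the reverse primer site is a design error
  broken <- paste0(substr(template, 1, 179), substr(template, 185, 200))
  expect_error(indel_amplicon_sizes(template, broken, fwd, rev_primer),
               class = "slafbsa_error_primer")
})

test_that("ORF length converts to peptide length", {
  expect_equal(orf_peptide_length(2241), 746)
  expect_equal(orf_peptide_length(6), 1)
  expect_error(orf_peptide_length(100), class = "slafbsa_error_domain")
})

test_that("the shipped enzyme table loads with valid definitions", {
  ez <- load_enzymes()
  expect_setequal(names(ez), c("AluI", "MluCI", "BstNI", "BsmAI", "EcoRI"))
  expect_true(ez$BsmAI$type_IIS)
  expect_false(ez$EcoRI$type_IIS)
})
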