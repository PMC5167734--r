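#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param pattern Recognition pattern, IUPAC nucleotide codes, length >= 4.
#' @param cut_offset Cut position on the top strand, counted in nucleotides
#'   from the start of the recognition pattern (0-based). Offsets beyond the
#'   pattern length describe type IIS enzymes that cut outside their site
#'   (flagged `type_IIS = TRUE`); cuts falling outside an amplicon are
#'   discarded during digestion.
#'
#' @return An object of class `enzyme_def`.
#' @export
#'
#' @examples
#' enzyme("EcoRI", "GAATTC", 1)
enzyme <- function(name, pattern, cut_offset) {
  pattern <- toupper(pattern)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(pattern, "")[[1]], iupac)
  if (length(bad) > 0L) {
    bsa_abort(sprintf("Invalid IUPAC code(s) in pattern: %s",
                      paste(bad, collapse = ", ")),
              "slafbsa_error_definition")
  }
  if (nchar(pattern) < 4L || cut_offset < 0) {
    bsa_abort("Pattern must be >= 4 nt and cut_offset >= 0.",
              "slafbsa_error_definition")
  }
  structure(list(name = name, pattern = pattern,
                 cut_offset = as.integer(cut_offset),
                 type_IIS = cut_offset > nchar(pattern)),
            class = "enzyme_def")
}

#' Load a restriction-enzyme definition table
#'
#' Reads a TSV with columns `name`, `pattern`, `cut_offset`. The table
#' shipped with the package seeds AluI, MluCI, BstNI, BsmAI and EcoRI with
#' their public recognition patterns and top-strand cut offsets.
#'
#' @param path Path to the TSV; defaults to the shipped table.
#' @return A list of [enzyme()] objects, named by enzyme.
#' @export
load_enzymes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "enzymes.tsv", package = "slafbsa")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ez <- purrr::pmap(tab[, c("name", "pattern", "cut_offset")], enzyme)
  stats::setNames(ez, tab$name)
}

#' Find restriction cut positions in a sequence
#'
#' Matches the enzyme's IUPAC recognition pattern on the forward strand and
#' its reverse complement (for non-palindromic sites), and maps every match
#' to a 0-based top-strand cut coordinate: `start + offset` for forward
#' matches and `start + pattern_length - offset` for reverse-orientation
#' matches. Palindromic sites are counted once (forward orientation wins).
#' Cuts outside `[0, length]` (possible for type IIS offsets) are discarded.
#'
#' @param seq Nucleotide string (ACGTN).
#' @param enz An [enzyme()].
#' @return Sorted, deduplicated integer vector of 0-based cut positions.
#' @export
#'
#' @examples
#' find_sites("GGAATTCC", enzyme("EcoRI", "GAATTC", 1))  # 2
find_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "enzyme_def"))
  if (grepl("[^ACGTNacgtn]", seq)) {
    bsa_abort("Sequence must use the alphabet ACGTN.", "slafbsa_error_format")
  }
  subject <- Biostrings::DNAString(toupper(seq))
  pat <- Biostrings::DNAString(enz$pattern)
  plen <- nchar(enz$pattern)
  fwd <- Biostrings::start(
    Biostrings::matchPattern(pat, subject, fixed = "subject"))
  rev <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                             fixed = "subject"))
  rev_only <- setdiff(rev, fwd)
  cuts <- c((fwd - 1L) + enz$cut_offset,
            (rev_only - 1L) + plen - enz$cut_offset)
  cuts <- sort(unique(cuts))
  cuts[cuts >= 0L & cuts <= nchar(seq)]
}

#' Predict digest fragment lengths
#'
#' Cut positions partition the interval `[0, length)`; fragment lengths are
#' returned in descending order. A sequence with no site yields a single
#' fragment of the full length; cuts at position 0 or at the end produce
#' zero-length fragments, which are dropped.
#'
#' @param seq Nucleotide string (the amplicon).
#' @param enz An [enzyme()].
#' @return Integer vector of fragment lengths (bp), descending; lengths
#'   always sum to the amplicon length.
#' @export
digest_fragments <- function(seq, enz) {
  len <- nchar(seq)
  cuts <- find_sites(seq, enz)
  frags <- diff(c(0L, cuts, len))
  sort(frags[frags > 0L], decreasing = TRUE)
}

# internal: multiset difference a \ b on integer vectors
.multiset_diff <- function(a, b) {
  for (x in b) {
    i <- match(x, a)
    if (!is.na(i)) a <- a[-i]
  }
  a
}

#' Rank enzymes by diagnostic power for two alleles
#'
#' An enzyme is diagnostic when its digest fragment-length multisets differ
#' between the two allele amplicons. Candidates are ranked by a gel
#' resolvability proxy: the minimum pairwise size difference between bands
#' unique to one allele and bands unique to the other (larger = easier to
#' score). Symmetric in allele order.
#'
#' @param seq_a,seq_b Allele amplicon sequences (same locus).
#' @param enzymes A list of [enzyme()] objects (e.g. from [load_enzymes()]).
#' @return A tibble of diagnostic enzymes, ranked by descending
#'   `min_band_diff`, with the fragment ladders of both alleles as
#'   comma-separated strings. Empty when no enzyme distinguishes the
#'   alleles.
#' @export
diagnostic_enzymes <- function(seq_a, seq_b, enzymes) {
  if (inherits(enzymes, "enzyme_def")) enzymes <- list(enzymes)
  rows <- purrr::map_dfr(enzymes, function(enz) {
    fa <- digest_fragments(seq_a, enz)
    fb <- digest_fragments(seq_b, enz)
    if (identical(as.integer(sort(fa)), as.integer(sort(fb)))) {
      return(tibble::tibble())
    }
    a_only <- .multiset_diff(fa, fb)
    b_only <- .multiset_diff(fb, fa)
    tibble::tibble(
      enzyme = enz$name,
      min_band_diff = min(abs(outer(a_only, b_only, `-`))),
      ladder_a = paste(fa, collapse = ","),
      ladder_b = paste(fb, collapse = ",")
    )
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(enzyme = character(), min_band_diff = numeric(),
                          ladder_a = character(), ladder_b = character()))
  }
  dplyr::arrange(rows, dplyr::desc(.data$min_band_diff), .data$enzyme)
}

# internal: exact matches of a primer (fwd on top strand, or the reverse
# primer's binding site = reverse complement on top strand)
.primer_matches <- function(template, primer, reverse = FALSE) {
  p <- Biostrings::DNAString(toupper(primer))
  if (reverse) p <- Biostrings::reverseComplement(p)
  Biostrings::matchPattern(p, Biostrings::DNAString(toupper(template)))
}

#' Predict InDel-marker amplicon sizes
#'
#' Requires each primer to match each allele template exactly once (forward
#' primer on the top strand, reverse primer on the bottom strand). Amplicon
#' size is the distance from the forward primer's first base to the last
#' base of the reverse primer's binding site, inclusive.
#'
#' @param seq_a,seq_b Allele template sequences.
#' @param primer_fwd,primer_rev Primer sequences (reverse primer given 5'->3'
#'   as synthesized).
#' @return A tibble with one row: `size_a`, `size_b`, `delta`
#'   (= `size_a - size_b`).
#' @export
indel_amplicon_sizes <- function(seq_a, seq_b, primer_fwd, primer_rev) {
  one_size <- function(template, label) {
    f <- .primer_matches(template, primer_fwd, reverse = FALSE)
    r <- .primer_matches(template, primer_rev, reverse = TRUE)
    if (length(f) != 1L || length(r) != 1L) {
      bsa_abort(sprintf(
        "Primer-design error on allele %s: forward matches %d time(s), reverse %d time(s); each primer must match exactly once.",
        label, length(f), length(r)), "slafbsa_error_primer")
    }
    size <- Biostrings::end(r) - Biostrings::start(f) + 1L
    if (size <= 0L) {
      bsa_abort(sprintf(
        "Primer-design error on allele %s: reverse site upstream of forward primer.",
        label), "slafbsa_error_primer")
    }
    size
  }
  sa <- one_size(seq_a, "a")
  sb <- one_size(seq_b, "b")
  tibble::tibble(size_a = sa, size_b = sb, delta = sa - sb)
}

#' Peptide length implied by an open reading frame
#'
#' An ORF of `orf_bp` base pairs encodes `orf_bp / 3` codons, one of which
#' is the stop; the peptide is one shorter.
#'
#' @param orf_bp ORF length in base pairs; must be a positive multiple of 3
#'   of at least 6 bp (start + stop).
#' @return Peptide length in amino acids.
#' @export
#'
#' @examples
#' orf_peptide_length(2241)  # 746
orf_peptide_length <- function(orf_bp) {
  if (any(orf_bp %% 3 != 0) || any(orf_bp < 6)) {
    bsa_abort("ORF length must be a multiple of 3 and at least 6 bp.",
              "slafbsa_error_domain")
  }
  orf_bp / 3 - 1
}
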