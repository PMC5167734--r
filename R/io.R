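#' Write and read the SLAF tag table
#'
#' Tab-separated with a header row. Columns on disk: `tag_id`, `chrom`,
#' `pos_cM`, `P_depth_high`, `M_depth_high`, `P_depth_low`, `M_depth_low`,
#' `parent_P_depth`, `parent_M_depth`, `n_snps`, plus `parent_P_M_depth` and
#' `parent_M_M_depth` so the per-parent allele composition round-trips.
#'
#' @param tags Tag tibble (see [simulate_tag_depths()]).
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); the tag tibble (reader).
#' @export
write_tag_table <- function(tags, path) {
  out <- tibble::tibble(
    tag_id = tags$tag_id, chrom = tags$chrom, pos_cM = tags$pos_cM,
    P_depth_high = tags$high_P, M_depth_high = tags$high_M,
    P_depth_low = tags$low_P, M_depth_low = tags$low_M,
    parent_P_depth = tags$parent_P_P + tags$parent_P_M,
    parent_M_depth = tags$parent_M_P + tags$parent_M_M,
    n_snps = tags$n_snps,
    parent_P_M_depth = tags$parent_P_M,
    parent_M_M_depth = tags$parent_M_M
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    tag_id = x$tag_id, chrom = as.character(x$chrom), pos_cM = x$pos_cM,
    n_snps = x$n_snps,
    parent_P_P = x$parent_P_depth - x$parent_P_M_depth,
    parent_P_M = x$parent_P_M_depth,
    parent_M_P = x$parent_M_depth - x$parent_M_M_depth,
    parent_M_M = x$parent_M_M_depth,
    high_P = x$P_depth_high, high_M = x$M_depth_high,
    low_P = x$P_depth_low, low_M = x$M_depth_low
  )
}

#' Write and read a genotype table
#'
#' Lines x loci codes (`P`/`M`/`H`) with a leading `line_id` column.
#'
#' @param pop A `ril_population`.
#' @param path TSV path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_genotypes <- function(pop, path) {
  g <- tibble::as_tibble(as.data.frame(pop$genotypes,
                                       stringsAsFactors = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(line_id = seq_len(pop$n_lines)), g)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a phenotype table
#'
#' @param phenotypes Tibble from [assign_phenotypes()].
#' @param path TSV path.
#' @param env Environment (season) label for the `env` column.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, env = "sim") {
  readr::write_tsv(
    tibble::tibble(line_id = phenotypes$line, env = env,
                   value = phenotypes$phenotype),
    path)
  invisible(path)
}

#' Write tag sequences to FASTA
#'
#' @param sequences Named character vector (e.g. from
#'   [simulate_tag_sequences()]).
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
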