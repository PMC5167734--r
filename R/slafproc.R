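#' Tag quality-filter policy
#'
#' @param min_parent_depth Minimum total tag depth required in *each* parent
#'   (default 5, i.e. tags below 5x in either parent are removed).
#' @param max_snps_per_tag Maximum SNPs allowed on a polymorphic tag
#'   (default 3; tags with more are removed).
#' @param min_cluster_identity Sequence identity above which tags are grouped
#'   into one locus (default 0.90, strict inequality).
#'
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_parent_depth = 5, max_snps_per_tag = 3,
                          min_cluster_identity = 0.90) {
  stopifnot(min_parent_depth >= 0, max_snps_per_tag >= 0,
            min_cluster_identity > 0, min_cluster_identity <= 1)
  structure(list(min_parent_depth = min_parent_depth,
                 max_snps_per_tag = max_snps_per_tag,
                 min_cluster_identity = min_cluster_identity),
            class = "filter_policy")
}

#' Quality-filter SLAF tags
#'
#' A tag is retained iff both parents' total tag depths are at least
#' `min_parent_depth` and the tag carries at most `max_snps_per_tag` SNPs
#' (boundaries inclusive). Rejected tags are logged with a reason:
#' `"low_depth"` (checked first) or `"too_many_snps"`.
#'
#' @param tags A tag tibble as produced by [simulate_tag_depths()] or
#'   [read_tag_table()].
#' @param policy A [filter_policy()].
#'
#' @return A list with elements `retained` (tag tibble) and `rejected`
#'   (tibble with `tag_id`, `reason`).
#' @export
filter_tags <- function(tags, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  tags <- tibble::as_tibble(tags)
  if (nrow(tags) == 0L) {
    return(list(retained = tags,
                rejected = tibble::tibble(tag_id = character(),
                                          reason = character())))
  }
  p_tot <- tags$parent_P_P + tags$parent_P_M
  m_tot <- tags$parent_M_P + tags$parent_M_M
  low <- p_tot < policy$min_parent_depth | m_tot < policy$min_parent_depth
  many <- tags$n_snps > policy$max_snps_per_tag
  reason <- dplyr::case_when(low ~ "low_depth",
                             many ~ "too_many_snps",
                             TRUE ~ NA_character_)
  list(
    retained = tags[is.na(reason), , drop = FALSE],
    rejected = tibble::tibble(tag_id = tags$tag_id[!is.na(reason)],
                              reason = reason[!is.na(reason)])
  )
}

# internal: pairwise identity between two split character vectors;
# N never matches (counts as mismatch on either side).
.hamming_identity <- function(a, b) {
  mean(a == b & a != "N" & b != "N")
}

#' Cluster equal-length tag sequences into loci
#'
#' Greedy single-pass clustering: sequences are processed in descending
#' total-depth order (ties keep input order); each sequence joins the first
#' existing cluster whose *representative* (founding sequence) it matches
#' with identity strictly greater than the threshold, otherwise it founds a
#' new cluster. Identity is the fraction of matching positions over the full
#' length; an `N` on either side matches nothing.
#'
#' @param sequences Character vector of equal-length nucleotide strings
#'   (alphabet ACGTN).
#' @param identity_threshold Identity that must be *exceeded* to join a
#'   cluster (default 0.90).
#' @param depths Optional numeric vector of total depths used to order
#'   processing; defaults to all-equal (input order).
#'
#' @return A tibble with one row per input sequence, in input order:
#'   `id` (input index or names), `cluster` (integer, numbered by founding
#'   order), `is_representative`.
#' @export
#'
#' @examples
#' cluster_tags(c("ACGTACGT", "ACGTACGA", "TTTTTTTT"), 0.8)
cluster_tags <- function(sequences, identity_threshold = 0.90, depths = NULL) {
  n <- length(sequences)
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (n == 0L) {
    return(tibble::tibble(id = character(), cluster = integer(),
                          is_representative = logical()))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bsa_abort("All sequences must have equal length.", "slafbsa_error_format")
  }
  if (any(grepl("[^ACGTN]", sequences))) {
    bsa_abort("Sequences must use the alphabet ACGTN.", "slafbsa_error_format")
  }
  depths <- depths %||% rep(0, n)
  stopifnot(length(depths) == n)
  ord <- order(-depths, seq_len(n))
  chars <- strsplit(sequences, "", fixed = TRUE)
  cluster <- integer(n)
  reps <- integer(0)                      # indices of cluster representatives
  for (i in ord) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      if (.hamming_identity(chars[[i]], chars[[reps[k]]]) >
          identity_threshold) {
        cluster[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  tibble::tibble(
    id = names(sequences) %||% as.character(seq_len(n)),
    cluster = cluster,
    is_representative = seq_len(n) %in% reps
  )
}

#' Call parent-polarized polymorphic markers
#'
#' A filtered tag is a polymorphic marker when the two parents are near-fixed
#' for opposite alleles: at least `purity` of the female parent's reads carry
#' the P allele and at least `purity` of the male parent's reads carry the M
#' allele. The purity cutoff (default 0.95) tolerates simulated sequencing
#' error; the underlying criterion is that each parent's tag genotype matches
#' that parent.
#'
#' @param tags Tag tibble that has passed [filter_tags()]; both parents must
#'   have nonzero depth (guaranteed by the depth filter).
#' @param purity Minimum within-parent allele purity (default 0.95).
#'
#' @return The marker subset of `tags`, ordered by `(chrom, pos_cM, tag_id)`.
#' @export
call_parent_markers <- function(tags, purity = 0.95) {
  tags <- tibble::as_tibble(tags)
  if (nrow(tags) == 0L) return(tags)
  p_tot <- tags$parent_P_P + tags$parent_P_M
  m_tot <- tags$parent_M_P + tags$parent_M_M
  if (any(p_tot == 0 | m_tot == 0)) {
    bsa_abort(
      "Zero parent depth after filtering: filter_tags contract violated.",
      "slafbsa_error_internal")
  }
  keep <- (tags$parent_P_P / p_tot >= purity) &
    (tags$parent_M_M / m_tot >= purity)
  tags[keep, , drop = FALSE] |>
    dplyr::arrange(.data$chrom, .data$pos_cM, .data$tag_id)
}
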