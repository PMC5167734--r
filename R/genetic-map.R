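#' Construct a genetic map
#'
#' A genetic map is a tibble of marker loci with their genetic positions in
#' centimorgans. Positions must be non-negative and strictly increasing
#' within a chromosome, and every chromosome must carry at least one locus.
#'
#' @param loci A data frame with columns `chrom` (chromosome name) and
#'   `pos_cM` (genetic position in centimorgans).
#'
#' @return A tibble of class `genetic_map` with columns `chrom` and `pos_cM`,
#'   ordered by chromosome (in order of first appearance) and position.
#' @export
#'
#' @examples
#' genetic_map(data.frame(chrom = "1A", pos_cM = c(0, 10, 25)))
genetic_map <- function(loci) {
  if (!is.data.frame(loci) || !all(c("chrom", "pos_cM") %in% names(loci))) {
    bsa_abort("`loci` must be a data frame with columns `chrom` and `pos_cM`.",
              "slafbsa_error_map")
  }
  map <- tibble::as_tibble(loci)[, c("chrom", "pos_cM")]
  map$chrom <- as.character(map$chrom)
  map$pos_cM <- as.numeric(map$pos_cM)
  if (nrow(map) < 1L || anyNA(map$pos_cM) || any(map$pos_cM < 0)) {
    bsa_abort("Map positions must be non-negative and non-missing.",
              "slafbsa_error_map")
  }
  # keep chromosomes in order of first appearance, positions as given
  map$chrom <- factor(map$chrom, levels = unique(map$chrom))
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos_cM) > 0) || dplyr::n() == 1L) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0L) {
    bsa_abort(
      paste0("Map positions must be strictly increasing within a chromosome ",
             "(violated on: ", paste(bad$chrom, collapse = ", "), ")."),
      "slafbsa_error_map")
  }
  map$chrom <- as.character(map$chrom)
  class(map) <- c("genetic_map", class(map))
  map
}

#' Build an evenly spaced genetic map
#'
#' Convenience constructor for simulation studies: `n_chrom` chromosomes,
#' each with `loci_per_chrom` loci evenly spaced from 0 to `length_cM`.
#'
#' @param n_chrom Number of chromosomes.
#' @param loci_per_chrom Loci (tag positions) per chromosome.
#' @param length_cM Chromosome length in centimorgans.
#' @param chrom_names Optional character vector of chromosome names; defaults
#'   to `"chr1"`, `"chr2"`, ...
#'
#' @return A `genetic_map` tibble.
#' @export
#'
#' @examples
#' make_genetic_map(3, loci_per_chrom = 5, length_cM = 100)
make_genetic_map <- function(n_chrom, loci_per_chrom, length_cM = 150,
                             chrom_names = NULL) {
  stopifnot(n_chrom >= 1, loci_per_chrom >= 1, length_cM >= 0)
  chrom_names <- chrom_names %||% paste0("chr", seq_len(n_chrom))
  stopifnot(length(chrom_names) == n_chrom)
  pos <- if (loci_per_chrom == 1L) 0 else
    seq(0, length_cM, length.out = loci_per_chrom)
  genetic_map(tibble::tibble(
    chrom = rep(chrom_names, each = loci_per_chrom),
    pos_cM = rep(pos, times = n_chrom)
  ))
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under the no-interference (Haldane) model:
#' \eqn{r = (1 - e^{-2d/100}) / 2}.
#'
#' @param d_cM Genetic distance(s) in centimorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}

# internal: per-interval recombination fractions for a concatenated map;
# chromosome boundaries get r = 0.5 (independent assortment).
.interval_r <- function(map) {
  L <- nrow(map)
  if (L < 2L) return(numeric(0))
  same <- map$chrom[-1L] == map$chrom[-L]
  r <- rep(0.5, L - 1L)
  r[same] <- haldane_r(diff(map$pos_cM)[same])
  r
}
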