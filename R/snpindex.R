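#' SNP index of a read pool
#'
#' Fraction of reads in a pool carrying the male-parent (M) allele:
#' `m / (p + m)`. Undefined (`NA`) when the pool has zero depth; such tags
#' are excluded downstream.
#'
#' @param m_depth M-allele read count(s).
#' @param p_depth P-allele read count(s).
#' @return Numeric vector of SNP indexes in `[0, 1]`, `NA` where depth is 0.
#' @export
#'
#' @examples
#' snp_index(3, 7)   # 0.3
#' snp_index(10, 0)  # 1
snp_index <- function(m_depth, p_depth) {
  if (any(m_depth < 0, na.rm = TRUE) || any(p_depth < 0, na.rm = TRUE)) {
    bsa_abort("Read counts must be non-negative.", "slafbsa_error_validation")
  }
  tot <- m_depth + p_depth
  out <- m_depth / tot
  out[tot == 0] <- NA_real_
  out
}

#' Difference of SNP indexes between bulks
#'
#' `delta = index_high - index_low`, in `[-1, 1]`. Near +1 at loci where the
#' high bulk is fixed for the M allele and the low bulk for the P allele.
#'
#' @param index_high SNP index of the high-trait bulk, in `[0, 1]`.
#' @param index_low SNP index of the low-trait bulk, in `[0, 1]`.
#' @return Numeric vector in `[-1, 1]` (`NA` propagates).
#' @export
delta_snp_index <- function(index_high, index_low) {
  rng <- suppressWarnings(range(c(index_high, index_low), na.rm = TRUE))
  if (length(index_high) && length(index_low) &&
      any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 1)) {
    bsa_abort("SNP indexes must lie in [0, 1].", "slafbsa_error_validation")
  }
  index_high - index_low
}

#' Empirical nearest-rank upper percentile
#'
#' Sorts the finite values ascending and returns the element at rank
#' `ceiling(q * N)` (no interpolation), so at most `floor((1 - q) * N)`
#' values strictly exceed the returned threshold.
#'
#' @param deltas Numeric vector (non-finite values are dropped).
#' @param q Percentile as a fraction (default 0.9999).
#' @return The threshold value.
#' @export
#'
#' @examples
#' percentile_threshold(1:100, 0.9999)  # 100
percentile_threshold <- function(deltas, q = 0.9999) {
  stopifnot(q > 0, q <= 1)
  d <- deltas[is.finite(deltas)]
  if (length(d) == 0L) {
    bsa_abort("No finite values to compute a threshold from.",
              "slafbsa_error_nodata")
  }
  s <- sort(d)
  # round() guards against floating-point overshoot of exact integer ranks
  r <- ceiling(round(q * length(s), 9))
  s[[min(max(r, 1L), length(s))]]
}

#' Detect hot regions of consecutive associated markers
#'
#' Flags each marker as associated (`delta >= threshold`, or
#' `|delta| >= threshold` with `two_sided = TRUE`); within each chromosome,
#' maximal runs of at least `min_run` consecutive associated markers (in
#' marker order, not a centimorgan window) become hot regions. Markers with
#' undefined delta are excluded before run detection.
#'
#' @param results Tibble with columns `tag_id`, `chrom`, `pos_cM`, `delta`,
#'   sorted by `(chrom, pos_cM)` (ties by `tag_id`); unsorted input is an
#'   error.
#' @param threshold Association threshold (e.g. from
#'   [percentile_threshold()]).
#' @param min_run Minimum run length (default 3).
#' @param two_sided Use `|delta|` instead of signed delta (default `FALSE`,
#'   as the scan is polarized toward the male-parent allele in the high
#'   bulk).
#'
#' @return A tibble of regions: `chrom`, `start_cM`, `end_cM`, `span_cM`,
#'   `n_markers`, `tag_ids` (comma-separated member tags).
#' @export
detect_hot_regions <- function(results, threshold, min_run = 3,
                               two_sided = FALSE) {
  results <- tibble::as_tibble(results)
  results <- results[!is.na(results$delta), , drop = FALSE]
  empty <- tibble::tibble(chrom = character(), start_cM = numeric(),
                          end_cM = numeric(), span_cM = numeric(),
                          n_markers = integer(), tag_ids = character())
  if (nrow(results) == 0L) return(empty)
  ord <- order(factor(results$chrom, levels = unique(results$chrom)),
               results$pos_cM, results$tag_id)
  if (!identical(ord, seq_len(nrow(results)))) {
    bsa_abort("`results` must be sorted by (chrom, pos_cM, tag_id).",
              "slafbsa_error_contract")
  }
  score <- if (two_sided) abs(results$delta) else results$delta
  results$associated <- score >= threshold
  out <- results |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      runs <- rle(df$associated)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- runs$values & runs$lengths >= min_run
      if (!any(keep)) {
        return(tibble::tibble(start_cM = numeric(), end_cM = numeric(),
                              span_cM = numeric(), n_markers = integer(),
                              tag_ids = character()))
      }
      purrr::map_dfr(which(keep), function(k) {
        i <- starts[k]:ends[k]
        tibble::tibble(
          start_cM = df$pos_cM[starts[k]],
          end_cM = df$pos_cM[ends[k]],
          span_cM = df$pos_cM[ends[k]] - df$pos_cM[starts[k]],
          n_markers = length(i),
          tag_ids = paste(df$tag_id[i], collapse = ",")
        )
      })
    }) |>
    dplyr::ungroup()
  out
}

#' Summarize hot regions
#'
#' One row per region plus a totals row (`chrom = "Total"`) with the summed
#' associated-marker count, mirroring a per-chromosome region report.
#'
#' @param regions Region tibble from [detect_hot_regions()].
#' @return A tibble with columns `chrom`, `start_cM`, `end_cM`, `span_cM`,
#'   `n_markers`.
#' @export
summarize_regions <- function(regions) {
  cols <- c("chrom", "start_cM", "end_cM", "span_cM", "n_markers")
  if (is.null(regions) || nrow(regions) == 0L) {
    body <- tibble::tibble(chrom = character(), start_cM = numeric(),
                           end_cM = numeric(), span_cM = numeric(),
                           n_markers = integer())
  } else {
    body <- tibble::as_tibble(regions)[, cols]
  }
  dplyr::bind_rows(
    body,
    tibble::tibble(chrom = "Total", start_cM = NA_real_, end_cM = NA_real_,
                   span_cM = NA_real_,
                   n_markers = sum(body$n_markers))
  )
}

#' Run a full SNP-index association scan
#'
#' Computes per-marker SNP indexes and delta(SNP index), derives the
#' empirical association threshold as the nearest-rank `q` percentile of the
#' defined deltas (unless `threshold` is supplied), and detects hot regions.
#'
#' @param markers Marker tibble from [call_parent_markers()] (or any tag
#'   tibble with the standard depth columns), sorted by `(chrom, pos_cM)`.
#' @param q Percentile for the empirical threshold (default 0.9999).
#' @param min_run Minimum consecutive associated markers per region
#'   (default 3).
#' @param two_sided Flag associations on `|delta|` (default `FALSE`).
#' @param threshold Optional fixed threshold overriding the percentile rule.
#'
#' @return An object of class `bsa_scan`: a list with `deltas` (per-marker
#'   tibble with `index_high`, `index_low`, `delta`, `associated`),
#'   `threshold`, `q`, `min_run`, `two_sided`, `regions`, and `n_excluded`
#'   (markers dropped for undefined indexes).
#' @export
bsa_scan <- function(markers, q = 0.9999, min_run = 3, two_sided = FALSE,
                     threshold = NULL) {
  markers <- tibble::as_tibble(markers)
  d <- markers |>
    dplyr::transmute(
      .data$tag_id, .data$chrom, .data$pos_cM,
      index_high = snp_index(.data$high_M, .data$high_P),
      index_low = snp_index(.data$low_M, .data$low_P),
      delta = delta_snp_index(.data$index_high, .data$index_low)
    )
  n_excluded <- sum(is.na(d$delta))
  d <- d[!is.na(d$delta), , drop = FALSE]
  if (is.null(threshold)) {
    threshold <- percentile_threshold(d$delta, q)
  }
  score <- if (two_sided) abs(d$delta) else d$delta
  d$associated <- score >= threshold
  regions <- detect_hot_regions(d, threshold, min_run = min_run,
                                two_sided = two_sided)
  structure(
    list(deltas = d, threshold = threshold, q = q, min_run = min_run,
         two_sided = two_sided, regions = regions, n_excluded = n_excluded),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf("<bsa_scan> %d markers (%d excluded), threshold %.4g, %d hot region(s)\n",
              nrow(x$deltas), x$n_excluded, x$threshold, nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions[, 1:5])
  invisible(x)
}

#' @rdname bsa_scan
#' @param x A `bsa_scan` object.
#' @param ... Unused.
#' @method tidy bsa_scan
#' @export
tidy.bsa_scan <- function(x, ...) x$deltas

#' @rdname bsa_scan
#' @method glance bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$deltas),
    n_excluded = x$n_excluded,
    threshold = x$threshold,
    n_associated = sum(x$deltas$associated),
    n_regions = nrow(x$regions),
    n_region_markers = sum(x$regions$n_markers)
  )
}

#' Plot a delta(SNP index) track
#'
#' Per-chromosome scatter of delta against genetic position with the
#' association threshold and detected hot regions highlighted.
#'
#' @param object A `bsa_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_scan
#' @export
autoplot.bsa_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$deltas,
                       ggplot2::aes(x = .data$pos_cM, y = .data$delta)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$associated),
                        size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Genetic position (cM)",
                  y = expression(Delta * "(SNP index)")) +
    ggplot2::theme_minimal()
  if (nrow(object$regions)) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start_cM - 0.5, xmax = .data$end_cM + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' @rdname autoplot.bsa_scan
#' @param scan A `bsa_scan` object.
#' @export
plot_delta_track <- function(scan, ...) autoplot(scan, ...)
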