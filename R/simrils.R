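#' Simulate a biparental recombinant inbred line (RIL) population
#'
#' Lines descend from a uniformly heterozygous F1 by single-seed-descent
#' selfing for `generation - 1` meioses per gamete. Each gamete is formed by
#' choosing a starting homolog at random and placing crossovers between
#' adjacent loci with the Haldane (no-interference) recombination fraction
#' implied by the inter-locus centimorgan distances; loci on different
#' chromosomes assort independently. At F8 the expected residual
#' heterozygosity per locus is \eqn{(1/2)^{7}}.
#'
#' @param map A [genetic_map()].
#' @param n_lines Number of lines to simulate.
#' @param generation Filial generation (>= 2); F8 corresponds to
#'   `generation = 8`, i.e. seven rounds of selfing from the F1.
#' @param seed Integer seed; identical seeds give bit-identical populations.
#'
#' @return An object of class `ril_population`: a list with elements
#'   `map` (the genetic map), `genotypes` (an `n_lines` x loci character
#'   matrix with codes `"P"` = female-parent homozygote, `"M"` = male-parent
#'   homozygote, `"H"` = residual heterozygote), `generation`, and `n_lines`.
#' @export
#'
#' @examples
#' map <- make_genetic_map(1, 20, 100)
#' pop <- simulate_ril_population(map, n_lines = 50, generation = 8, seed = 1)
#' table(pop$genotypes[, 1])
simulate_ril_population <- function(map, n_lines, generation = 8, seed) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  stopifnot(n_lines >= 1, generation >= 2)
  L <- nrow(map)
  rprob <- .interval_r(map)
  h <- withr::with_seed(seed, {
    h1 <- matrix(0L, n_lines, L)   # F1: one intact P homolog ...
    h2 <- matrix(1L, n_lines, L)   # ... and one intact M homolog
    for (g in seq_len(generation - 1L)) {
      g1 <- .meiosis(h1, h2, rprob)
      g2 <- .meiosis(h1, h2, rprob)
      h1 <- g1
      h2 <- g2
    }
    list(h1, h2)
  })
  dosage <- h[[1]] + h[[2]]                 # 0, 1, 2 copies of the M allele
  codes <- matrix(c("P", "H", "M")[dosage + 1L], n_lines, L)
  colnames(codes) <- paste0(map$chrom, "@", format(map$pos_cM, trim = TRUE))
  structure(
    list(map = map, genotypes = codes,
         generation = as.integer(generation), n_lines = as.integer(n_lines)),
    class = "ril_population"
  )
}

# internal: one gamete per line from homolog matrices h1/h2 (0/1 alleles).
# rprob: per-interval recombination fractions (length ncol - 1).
.meiosis <- function(h1, h2, rprob) {
  n <- nrow(h1)
  L <- ncol(h1)
  start <- stats::rbinom(n, 1L, 0.5)
  if (L == 1L) {
    pick <- matrix(start, n, 1L)
  } else {
    sw <- matrix(stats::rbinom(n * (L - 1L), 1L, rep(rprob, each = n)),
                 n, L - 1L)
    cum <- t(apply(cbind(start, sw), 1L, cumsum)) %% 2L
    pick <- cum
  }
  h1 * (1L - pick) + h2 * pick
}

#' @export
print.ril_population <- function(x, ...) {
  cat(sprintf("<ril_population> F%d, %d lines x %d loci on %d chromosome(s)\n",
              x$generation, x$n_lines, ncol(x$genotypes),
              length(unique(x$map$chrom))))
  het <- mean(x$genotypes == "H")
  cat(sprintf("  residual heterozygosity: %.4f (expected %.4f)\n",
              het, 0.5^(x$generation - 1)))
  invisible(x)
}

#' Tidy a RIL population into long format
#'
#' @param x A `ril_population`.
#' @param ... Unused.
#' @return A tibble with one row per line x locus: `line`, `chrom`, `pos_cM`,
#'   `genotype`.
#' @method tidy ril_population
#' @export
tidy.ril_population <- function(x, ...) {
  tibble::tibble(
    line = rep(seq_len(x$n_lines), times = nrow(x$map)),
    chrom = rep(x$map$chrom, each = x$n_lines),
    pos_cM = rep(x$map$pos_cM, each = x$n_lines),
    genotype = as.vector(x$genotypes)
  )
}

#' Specify a phenotype model
#'
#' An additive single- or multi-QTL model: phenotype = `mu` + sum of QTL
#' effects + Normal(0, `sigma_e`) noise. Genotype coding at each QTL is
#' P = -1, M = +1, H = 0, so a QTL of additive effect `a` separates the two
#' homozygote classes by `2a`. Under balanced +/- a coding the
#' single-QTL phenotypic variance explained is `a^2 / (a^2 + sigma_e^2)`.
#'
#' @param mu Trait mean (e.g. grams for thousand-grain weight).
#' @param sigma_e Residual standard deviation (same units); must be >= 0.
#' @param qtl `NULL` (no QTL) or a data frame with columns `chrom`, `pos_cM`,
#'   `effect` (additive effect in trait units).
#'
#' @return An object of class `phenotype_model`.
#' @export
#'
#' @examples
#' phenotype_model(mu = 30, sigma_e = 5,
#'                 qtl = data.frame(chrom = "chr1", pos_cM = 50,
#'                                  effect = effect_for_pve(0.25, 5)))
phenotype_model <- function(mu, sigma_e, qtl = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(sigma_e), length(sigma_e) == 1L, sigma_e >= 0)
  if (!is.null(qtl)) {
    if (!is.data.frame(qtl) ||
        !all(c("chrom", "pos_cM", "effect") %in% names(qtl))) {
      bsa_abort("`qtl` must have columns chrom, pos_cM, effect.",
                "slafbsa_error_config")
    }
    qtl <- tibble::as_tibble(qtl)
    qtl$chrom <- as.character(qtl$chrom)
  }
  structure(list(mu = mu, sigma_e = sigma_e, qtl = qtl),
            class = "phenotype_model")
}

#' Additive effect for a target single-QTL variance fraction
#'
#' Solves `a^2 / (a^2 + sigma_e^2) = pve` for the additive effect `a`, the
#' planted-QTL calibration used by the simulator.
#'
#' @param pve Target phenotypic variance explained, in `[0, 1)`.
#' @param sigma_e Residual standard deviation.
#' @return The additive effect `a` (trait units).
#' @export
effect_for_pve <- function(pve, sigma_e) {
  stopifnot(pve >= 0, pve < 1, sigma_e >= 0)
  sigma_e * sqrt(pve / (1 - pve))
}

#' Assign phenotypes to a RIL population
#'
#' Each QTL is snapped to the nearest map locus on its chromosome, so the
#' genotype matrix remains the single source of genetic state.
#'
#' @param pop A `ril_population`.
#' @param model A [phenotype_model()].
#' @param seed Integer seed; identical seeds give identical phenotypes.
#'
#' @return A tibble with columns `line` and `phenotype`.
#' @export
assign_phenotypes <- function(pop, model, seed) {
  stopifnot(inherits(pop, "ril_population"), inherits(model, "phenotype_model"))
  n <- pop$n_lines
  genetic <- rep(0, n)
  if (!is.null(model$qtl) && nrow(model$qtl) > 0L) {
    for (i in seq_len(nrow(model$qtl))) {
      q <- model$qtl[i, ]
      on_chrom <- which(pop$map$chrom == q$chrom)
      if (length(on_chrom) == 0L) {
        bsa_abort(sprintf("QTL chromosome '%s' is absent from the map.",
                          q$chrom), "slafbsa_error_config")
      }
      locus <- on_chrom[which.min(abs(pop$map$pos_cM[on_chrom] - q$pos_cM))]
      code <- c(P = -1, H = 0, M = 1)[pop$genotypes[, locus]]
      genetic <- genetic + q$effect * unname(code)
    }
  }
  noise <- withr::with_seed(seed, stats::rnorm(n, 0, model$sigma_e))
  tibble::tibble(line = seq_len(n), phenotype = model$mu + genetic + noise)
}

#' Select extreme phenotype bulks
#'
#' Lines are stably sorted by (phenotype, line index); the low bulk is the
#' first `bulk_size` lines of that order and the high bulk the last
#' `bulk_size`. With distinct phenotypes this selects the smallest and
#' largest values; exact ties are resolved deterministically by line index.
#'
#' @param phenotypes A tibble from [assign_phenotypes()] (columns `line`,
#'   `phenotype`) or a bare numeric vector.
#' @param bulk_size Lines per bulk; `2 * bulk_size` must not exceed the
#'   population size.
#'
#' @return A list with integer line-index vectors `high` and `low`
#'   (each sorted ascending, disjoint).
#' @export
#'
#' @examples
#' select_bulks(c(5, 1, 3, 9, 7, 2), bulk_size = 2)
select_bulks <- function(phenotypes, bulk_size = 30) {
  v <- if (is.data.frame(phenotypes)) phenotypes$phenotype else phenotypes
  n <- length(v)
  if (anyNA(v)) {
    bsa_abort("Phenotypes must not be missing for bulk selection.",
              "slafbsa_error_design")
  }
  if (2L * bulk_size > n) {
    bsa_abort(sprintf(
      "2 x bulk_size (%d) exceeds the population size (%d).",
      2L * bulk_size, n), "slafbsa_error_design")
  }
  ord <- order(v, seq_along(v))
  list(high = sort(ord[(n - bulk_size + 1L):n]),
       low = sort(ord[seq_len(bulk_size)]))
}

#' Sequencing-depth simulation parameters
#'
#' @param mean_depth Expected reads per tag per source (parents and bulks
#'   share it). `0` is allowed as a degenerate diagnostic setting in which
#'   every depth is zero and all tags are later excluded as undefined.
#' @param error_rate Probability a read reports the wrong parental allele
#'   (symmetric flip); must be in `[0, 0.5)`.
#'
#' @return An object of class `seq_sim_params`.
#' @export
seq_sim_params <- function(mean_depth = 50, error_rate = 0.001) {
  stopifnot(mean_depth >= 0, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_depth = mean_depth, error_rate = error_rate),
            class = "seq_sim_params")
}

#' Simulate per-tag read depths for parents and bulks
#'
#' One tag per map locus. For each tag and source the total depth is
#' Poisson(`mean_depth`); the male-parent (M) allele read count is
#' Binomial(depth, f'), with f the M-allele frequency among the source's
#' lines (heterozygotes contribute 1/2; parents have f = 0 and f = 1) and
#' f' = f(1 - e) + (1 - f)e the error-perturbed frequency. The number of
#' SNPs on each tag is drawn as 1 + Poisson(0.5).
#'
#' @param pop A `ril_population`.
#' @param bulks Bulk line indices from [select_bulks()].
#' @param params A [seq_sim_params()].
#' @param seed Integer seed.
#'
#' @return A tibble of SLAF tags with columns `tag_id`, `chrom`, `pos_cM`,
#'   `n_snps`, and P/M allele read counts per source:
#'   `parent_P_P`, `parent_P_M`, `parent_M_P`, `parent_M_M`,
#'   `high_P`, `high_M`, `low_P`, `low_M`.
#' @export
simulate_tag_depths <- function(pop, bulks, params = seq_sim_params(), seed) {
  stopifnot(inherits(pop, "ril_population"), inherits(params, "seq_sim_params"))
  n <- pop$n_lines
  idx <- c(bulks$high, bulks$low)
  if (any(idx < 1L | idx > n)) {
    bsa_abort("Bulk line index out of range.", "slafbsa_error_index")
  }
  L <- nrow(pop$map)
  dos <- matrix(c(P = 0, H = 0.5, M = 1)[pop$genotypes], nrow(pop$genotypes))
  f <- list(
    parent_P = rep(0, L),
    parent_M = rep(1, L),
    high = colMeans(dos[bulks$high, , drop = FALSE]),
    low = colMeans(dos[bulks$low, , drop = FALSE])
  )
  e <- params$error_rate
  counts <- withr::with_seed(seed, {
    n_snps <- 1L + stats::rpois(L, 0.5)
    out <- list(n_snps = n_snps)
    for (src in names(f)) {
      depth <- stats::rpois(L, params$mean_depth)
      fp <- f[[src]] * (1 - e) + (1 - f[[src]]) * e
      m <- stats::rbinom(L, depth, fp)
      out[[paste0(src, "_M")]] <- m
      out[[paste0(src, "_P")]] <- depth - m
    }
    out
  })
  tibble::tibble(
    tag_id = sprintf("SLAF%06d", seq_len(L)),
    chrom = pop$map$chrom,
    pos_cM = pop$map$pos_cM,
    n_snps = counts$n_snps,
    parent_P_P = counts$parent_P_P, parent_P_M = counts$parent_P_M,
    parent_M_P = counts$parent_M_P, parent_M_M = counts$parent_M_M,
    high_P = counts$high_P, high_M = counts$high_M,
    low_P = counts$low_P, low_M = counts$low_M
  )
}

#' Simulate synthetic SLAF tag sequences
#'
#' Random nucleotide sequences mimicking size-selected restriction fragments
#' (default length range 464-484 bp). Purely synthetic; used for exercising
#' sequence clustering and FASTA output.
#'
#' @param n_tags Number of sequences.
#' @param seed Integer seed.
#' @param length_range Two-element integer range of fragment lengths (bp).
#' @return A named character vector (names `SLAF000001`, ...).
#' @export
simulate_tag_sequences <- function(n_tags, seed, length_range = c(464L, 484L)) {
  stopifnot(n_tags >= 1, length(length_range) == 2L,
            length_range[1] <= length_range[2])
  withr::with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_tags,
                   replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("SLAF%06d", seq_len(n_tags))
    seqs
  })
}
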