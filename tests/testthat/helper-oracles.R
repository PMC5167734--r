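# Independent oracles used across the suite. Each is a deliberately simple,
# brute-force formulation kept separate from the implementation it checks.

# Exact two-locus genotype distribution under repeated selfing from a
# coupling-phase F1, by enumeration over the 10 unordered pairs of two-locus
# gametes. `r` is the per-meiosis recombination fraction between the loci.
# Returns the probability vector over unordered gamete pairs at the given
# filial generation, with helpers for the quantities the tests need.
two_locus_selfing_oracle <- function(r, generation) {
  gam <- c("PP", "PM", "MP", "MM")
  gamete_dist <- function(a, b) {
    p <- stats::setNames(numeric(4), gam)
    if (a == b) {
      p[a] <- 1
      return(p)
    }
    a1 <- substr(a, 1, 1); a2 <- substr(a, 2, 2)
    b1 <- substr(b, 1, 1); b2 <- substr(b, 2, 2)
    for (h in list(c(paste0(a1, a2), (1 - r) / 2),
                   c(paste0(b1, b2), (1 - r) / 2),
                   c(paste0(a1, b2), r / 2),
                   c(paste0(b1, a2), r / 2))) {
      p[h[1]] <- p[h[1]] + as.numeric(h[2])
    }
    p
  }
  pairs <- list()
  for (i in 1:4) for (j in i:4) pairs <- c(pairs, list(c(gam[i], gam[j])))
  pair_name <- vapply(pairs, paste, character(1), collapse = "/")
  trans <- matrix(0, length(pairs), length(pairs),
                  dimnames = list(pair_name, pair_name))
  for (k in seq_along(pairs)) {
    gd <- gamete_dist(pairs[[k]][1], pairs[[k]][2])
    for (i in 1:4) for (j in i:4) {
      pr <- if (i == j) gd[i]^2 else 2 * gd[i] * gd[j]
      trans[k, paste(gam[i], gam[j], sep = "/")] <-
        trans[k, paste(gam[i], gam[j], sep = "/")] + pr
    }
  }
  v <- stats::setNames(numeric(length(pairs)), pair_name)
  v["PP/MM"] <- 1                      # F1: intact parental homologs
  for (g in seq_len(generation - 1)) v <- drop(v %*% trans)
  hom_both <- v[c("PP/PP", "MM/MM", "PM/PM", "MP/MP")]
  list(
    state_prob = v,
    # recombinant fraction among lines homozygous at both loci
    recomb_frac_hom = sum(v[c("PM/PM", "MP/MP")]) / sum(hom_both),
    p_hom_both = sum(hom_both),
    p_double_recomb_hom = sum(v[c("PM/PM", "MP/MP")])
  )
}

# Brute-force greedy clustering oracle: all-pairs Hamming identities computed
# from integer codepoints, then the greedy assignment replayed with plain
# loops. Independent of cluster_tags' internals.
cluster_oracle <- function(sequences, threshold, depths = NULL) {
  n <- length(sequences)
  depths <- if (is.null(depths)) rep(0, n) else depths
  ints <- lapply(sequences, utf8ToInt)
  n_int <- utf8ToInt("N")
  ident <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    same <- ints[[i]] == ints[[j]] & ints[[i]] != n_int & ints[[j]] != n_int
    ident[i, j] <- sum(same) / length(ints[[i]])
  }
  ord <- order(-depths, seq_len(n))
  cluster <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (ident[i, reps[k]] > threshold) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    } else {
      cluster[i] <- hit
    }
  }
  list(cluster = cluster, identity = ident, reps = reps)
}

# Nearest-rank percentile by its counting definition: the smallest sorted
# value whose cumulative count reaches q * N.
nearest_rank_oracle <- function(x, q) {
  s <- sort(x[is.finite(x)])
  n <- length(s)
  s[which(seq_len(n) >= q * n - 1e-9)[1]]
}

# Hand computation of two-class ANOVA sums of squares.
ss_oracle <- function(values, groups) {
  gm <- mean(values)
  ssb <- 0
  ssw <- 0
  for (k in unique(groups)) {
    v <- values[groups == k]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  list(ssb = ssb, ssw = ssw, sst = ssb + ssw)
}

# A hand-built RIL population object for depth-model tests: genotype codes
# supplied directly, bypassing the meiosis simulator.
manual_population <- function(codes, chrom = "chr1",
                              pos = seq_len(ncol(codes)) - 1) {
  map <- genetic_map(data.frame(chrom = chrom, pos_cM = pos))
  structure(list(map = map, genotypes = codes,
                 generation = 8L, n_lines = nrow(codes)),
            class = "ril_population")
}

# Random ACGT string of length n (test construction helper).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
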