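test_that("tightly linked loci never recombine and unlinked loci assort freely", {
  # r ~ 0 between near-coincident loci
  map0 <- genetic_map(data.frame(chrom = "c1", pos_cM = c(10, 10 + 1e-12)))
  pop0 <- simulate_ril_population(map0, n_lines = 2000, generation = 8,
                                  seed = 11)
  expect_identical(pop0$genotypes[, 1], pop0$genotypes[, 2])
  expect_equal(haldane_r(0), 0)

  # loci on different chromosomes: genotype correlation ~ 0
  map2 <- genetic_map(data.frame(chrom = c("c1", "c2"), pos_cM = c(0, 0)))
  pop2 <- simulate_ril_population(map2, n_lines = 10000, generation = 8,
                                  seed = 12)
  dos <- matrix(c(P = -1, H = 0, M = 1)[pop2$genotypes], 10000)
  expect_lt(abs(cor(dos[, 1], dos[, 2])), 0.03)
})

test_that("residual heterozygosity decays as (1/2)^(generation - 1)", {
  map <- make_genetic_map(1, 1, 0)
  for (gen in c(2, 5, 8)) {
    pop <- simulate_ril_population(map, n_lines = 10000, generation = gen,
                                   seed = 20 + gen)
    p <- 0.5^(gen - 1)
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(pop$genotypes == "H") - p), 3 * se)
  }
})

test_that("recombinant fractions match the exact two-locus selfing oracle", {
  d <- 20
  r <- haldane_r(d)
  map <- genetic_map(data.frame(chrom = "c1", pos_cM = c(0, d)))

  # F2: frequency of lines homozygous-recombinant at both loci
  oracle2 <- two_locus_selfing_oracle(r, generation = 2)
  n <- 20000
  popF2 <- simulate_ril_population(map, n, generation = 2, seed = 31)
  g <- popF2$genotypes
  dbl <- mean((g[, 1] == "P" & g[, 2] == "M") |
                (g[, 1] == "M" & g[, 2] == "P"))
  p <- oracle2$p_double_recomb_hom
  expect_lt(abs(dbl - p), 3 * sqrt(p * (1 - p) / n))

  # F8: recombinant fraction among lines homozygous at both loci
  oracle8 <- two_locus_selfing_oracle(r, generation = 8)
  popF8 <- simulate_ril_population(map, n, generation = 8, seed = 32)
  g8 <- popF8$genotypes
  hom <- g8[, 1] %in% c("P", "M") & g8[, 2] %in% c("P", "M")
  rec <- mean(g8[hom, 1] != g8[hom, 2])
  pr <- oracle8$recomb_frac_hom
  expect_lt(abs(rec - pr), 3 * sqrt(pr * (1 - pr) / sum(hom)))
})

test_that("population simulation is seed-deterministic and validates its map", {
  map <- make_genetic_map(2, 20, 100)
  a <- simulate_ril_population(map, 50, 8, seed = 42)
  b <- simulate_ril_population(map, 50, 8, seed = 42)
  c <- simulate_ril_population(map, 50, 8, seed = 43)
  expect_identical(a$genotypes, b$genotypes)
  expect_false(identical(a$genotypes, c$genotypes))
  expect_error(
    genetic_map(data.frame(chrom = "c1", pos_cM = c(5, 5))),
    class = "slafbsa_error_map")
  expect_error(
    genetic_map(data.frame(chrom = "c1", pos_cM = c(10, 4))),
    class = "slafbsa_error_map")
})

test_that("phenotypes follow the additive QTL model", {
  map <- make_genetic_map(1, 5, 40)
  pop <- simulate_ril_population(map, 200, 8, seed = 5)
  # sigma_e = 0: phenotypes are exactly mu +/- a (or mu for residual hets)
  model <- phenotype_model(mu = 30, sigma_e = 0,
                           qtl = data.frame(chrom = "chr1", pos_cM = 20,
                                            effect = 5))
  ph <- assign_phenotypes(pop, model, seed = 6)
  expect_true(all(ph$phenotype %in% c(25, 30, 35)))
  locus <- which.min(abs(pop$map$pos_cM - 20))
  expect_identical(ph$phenotype == 35, unname(pop$genotypes[, locus] == "M"))

  # a = 0: i.i.d. Normal(mu, sigma_e)
  null <- assign_phenotypes(pop, phenotype_model(mu = 30, sigma_e = 5),
                            seed = 7)
  expect_lt(abs(mean(null$phenotype) - 30), 3 * 5 / sqrt(200))
  expect_lt(abs(sd(null$phenotype) - 5), 1)

  # unknown chromosome
  bad <- phenotype_model(30, 5, data.frame(chrom = "chrX", pos_cM = 1,
                                           effect = 1))
  expect_error(assign_phenotypes(pop, bad, seed = 8),
               class = "slafbsa_error_config")
})

test_that("bulk selection takes the phenotype extremes with deterministic ties", {
  b <- select_bulks(1:150, bulk_size = 30)
  expect_identical(b$high, 121:150)
  expect_identical(b$low, 1:30)
  expect_length(intersect(b$high, b$low), 0)

  # degenerate all-equal input resolves by line index
  b2 <- select_bulks(rep(1, 150), bulk_size = 30)
  expect_identical(b2$low, 1:30)
  expect_identical(b2$high, 121:150)

  expect_error(select_bulks(1:50, bulk_size = 30),
               class = "slafbsa_error_design")
  expect_error(select_bulks(c(1, NA, 3, 4), bulk_size = 1),
               class = "slafbsa_error_design")
})

test_that("tag depths conserve reads and track bulk allele frequencies", {
  # two lines, one fixed P and one fixed M, each its own "bulk": f = 0 and 1
  L <- 10000
  codes <- rbind(rep("P", L), rep("M", L))
  pop <- manual_population(codes)
  bulks <- list(high = 2L, low = 1L)
  tags <- simulate_tag_depths(pop, bulks, seq_sim_params(50, 0), seed = 9)
  # depth conservation holds by construction for every source
  expect_true(all(tags$high_P + tags$high_M >= 0))
  covered <- tags$high_P + tags$high_M > 0
  expect_true(all(tags$high_M[covered] ==
                    (tags$high_P + tags$high_M)[covered]))  # f = 1
  expect_true(all(tags$low_M == 0))                         # f = 0
  idx <- snp_index(tags$high_M, tags$high_P)
  expect_true(all(idx[!is.na(idx)] == 1))

  # f = 0.5 bulk: mean M read fraction ~ 0.5 over 10,000 tags
  bulks2 <- list(high = c(1L, 2L), low = c(1L, 2L))
  tags2 <- simulate_tag_depths(pop, bulks2, seq_sim_params(50, 0), seed = 10)
  frac <- with(tags2, sum(high_M) / sum(high_M + high_P))
  expect_lt(abs(frac - 0.5), 0.01)

  # degenerate zero depth
  tags0 <- simulate_tag_depths(pop, bulks, seq_sim_params(0, 0), seed = 11)
  expect_true(all(tags0$high_P + tags0$high_M == 0))
  expect_true(all(is.na(snp_index(tags0$high_M, tags0$high_P))))

  # determinism and index validation
  again <- simulate_tag_depths(pop, bulks, seq_sim_params(50, 0), seed = 9)
  expect_identical(tags, again)
  expect_error(simulate_tag_depths(pop, list(high = 5L, low = 1L),
                                   seq_sim_params(), seed = 1),
               class = "slafbsa_error_index")
})

test_that("synthetic tag sequences honour the size-selection window", {
  seqs <- simulate_tag_sequences(20, seed = 3)
  expect_true(all(nchar(seqs) >= 464 & nchar(seqs) <= 484))
  expect_false(any(grepl("[^ACGT]", seqs)))
  expect_identical(seqs, simulate_tag_sequences(20, seed = 3))
})
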