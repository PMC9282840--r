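# Synthetic cohort generator: allele frequencies, LD structure, liability
# phenotype, sumstats calibration, and file round-trips.

test_that("genotype simulation respects MAF targets and block structure", {
  spec1 <- ld_block_spec(1, 1, 0, c(0.3, 0.3))
  g1 <- simulate_ld_genotypes(1000, spec1, seed = 1)
  expect_true(all(g1$genotypes %in% 0:2))
  expect_lt(abs(mean(g1$genotypes) / 2 - 0.3), 0.03)

  spec2 <- ld_block_spec(4, 2, 0.9, c(0.3, 0.4))
  g2 <- simulate_ld_genotypes(10000, spec2, seed = 2)
  geno <- g2$genotypes
  adj_r2 <- sapply(c(1:3, 5:7), function(k)
    stats::cor(geno[, k], geno[, k + 1])^2)
  # band frozen from a 20-replicate Monte-Carlo of this generator at
  # latent r = 0.9 (realized genotype r2 averages 0.494, range 0.48-0.50)
  expect_gt(mean(adj_r2), 0.45)
  expect_lt(mean(adj_r2), 0.55)
  cross <- abs(stats::cor(geno[, 1:4], geno[, 5:8]))
  expect_lt(mean(cross), 0.05)
  # blocks separated by > 500 kb
  expect_gt(g2$variants$pos[5] - g2$variants$pos[4], 500000)
  expect_false(is.unsorted(g2$variants$pos, strictly = TRUE))
})

test_that("fixing the seed fixes every simulated output bit-identically", {
  spec <- ld_block_spec(3, 4, 0.5, c(0.1, 0.4))
  g_a <- simulate_ld_genotypes(50, spec, seed = 99)
  g_b <- simulate_ld_genotypes(50, spec, seed = 99)
  expect_identical(g_a, g_b)
  arch <- planted_architecture(
    list(list(snps = g_a$variants$snp_id[1:3], disease_effect = 0.2,
              longevity_effect = -0.1)), gwas_n = 1000)
  expect_identical(simulate_phenotype(g_a$genotypes, arch, seed = 5),
                   simulate_phenotype(g_b$genotypes, arch, seed = 5))
  expect_identical(
    simulate_sumstats(g_a$genotypes, g_a$variants, arch, seed = 6),
    simulate_sumstats(g_b$genotypes, g_b$variants, arch, seed = 6))
})

test_that("invalid generator and architecture parameters are rejected", {
  expect_error(ld_block_spec(0, 1), "positive")
  expect_error(ld_block_spec(3, 2, within_block_r = 1), "multi-SNP")
  expect_error(ld_block_spec(1, 1, maf_range = c(0, 0.3)), "maf_range")
  expect_error(planted_architecture(list(), gwas_n = 10), "gwas_n")
  expect_error(
    planted_architecture(list(list(snps = "a", disease_effect = 1,
                                   longevity_effect = 0),
                              list(snps = "a", disease_effect = 0,
                                   longevity_effect = 0)),
                         gwas_n = 100), "disjoint")
  expect_error(
    planted_architecture(list(), gwas_n = 100, prevalence = 0), "prevalence")
})

test_that("liability phenotype hits the prevalence and planted effects", {
  spec <- ld_block_spec(1, 2, 0, c(0.3, 0.4))
  g <- simulate_ld_genotypes(10000, spec, seed = 3)
  null_arch <- planted_architecture(list(), gwas_n = 1000, prevalence = 0.5)
  ph <- simulate_phenotype(g$genotypes, null_arch, seed = 4)
  expect_lt(abs(mean(ph) - 0.5), 0.02)

  arch <- planted_architecture(
    list(list(snps = g$variants$snp_id[1], disease_effect = 0,
              longevity_effect = 1.0)), gwas_n = 1000)
  ph2 <- simulate_phenotype(g$genotypes, arch, seed = 4)
  refit <- stats::glm(ph2 ~ g$genotypes[, 1], family = stats::binomial())
  expect_gt(exp(stats::coef(refit)[2]), 1)

  bad <- planted_architecture(
    list(list(snps = "nope", disease_effect = 0, longevity_effect = 1)),
    gwas_n = 1000)
  expect_error(simulate_phenotype(g$genotypes, bad, seed = 1), "absent")
})

test_that("doubling a longevity effect does not reduce the refit OR", {
  spec <- ld_block_spec(1, 1, 0, c(0.3, 0.3))
  beta_small <- beta_large <- numeric(20)
  for (r in 1:20) {
    g <- simulate_ld_genotypes(600, spec, seed = 500 + r)
    for (eff in c(0.3, 0.6)) {
      arch <- planted_architecture(
        list(list(snps = g$variants$snp_id[1], disease_effect = 0,
                  longevity_effect = eff)), gwas_n = 1000)
      ph <- simulate_phenotype(g$genotypes, arch, seed = 700 + r)
      b <- stats::coef(stats::glm(ph ~ g$genotypes[, 1],
                                  family = stats::binomial()))[2]
      if (eff == 0.3) beta_small[r] <- b else beta_large[r] <- b
    }
  }
  expect_gt(mean(beta_large), mean(beta_small))
})

test_that("simulated sumstats are calibrated under the null", {
  spec <- ld_block_spec(1, 1000, 0, c(0.2, 0.4))
  g <- simulate_ld_genotypes(2, spec, seed = 8)
  null_arch <- planted_architecture(list(), gwas_n = 100000)
  ss <- simulate_sumstats(g$genotypes, g$variants, null_arch, seed = 9)
  ks <- stats::ks.test(ss$p, "punif")
  expect_gt(ks$p.value, 0.01)
  # p is the two-sided normal tail of beta / se
  expect_equal(ss$p, 2 * stats::pnorm(-abs(ss$beta / ss$se)),
               tolerance = 1e-12)
  expect_equal(ss$se, 1 / sqrt(2 * 100000 * g$variants$maf *
                                 (1 - g$variants$maf)), tolerance = 1e-12)
})

test_that("larger planted effects give stochastically smaller p-values", {
  spec <- ld_block_spec(1, 200, 0, c(0.25, 0.35))
  g <- simulate_ld_genotypes(2, spec, seed = 10)
  ids <- g$variants$snp_id
  arch <- planted_architecture(
    list(list(snps = ids[1:100], disease_effect = 0.4, longevity_effect = 0),
         list(snps = ids[101:200], disease_effect = 0.02,
              longevity_effect = 0)), gwas_n = 50000)
  ss <- simulate_sumstats(g$genotypes, g$variants, arch, seed = 11)
  expect_lt(median(ss$p[1:100]), median(ss$p[101:200]))
})

test_that("fixture bundle round-trips through the package readers", {
  spec <- ld_block_spec(2, 3, 0.4, c(0.2, 0.4))
  g <- simulate_ld_genotypes(30, spec, seed = 12)
  g$genotypes[1, 2] <- NA  # exercise missing genotype encoding
  arch <- planted_architecture(
    list(list(snps = g$variants$snp_id[1:2], disease_effect = 0.3,
              longevity_effect = -0.2)), gwas_n = 5000)
  ph <- simulate_phenotype(g$genotypes, arch, seed = 13)
  ss <- simulate_sumstats(g$genotypes, g$variants, arch, seed = 14)
  sets <- annotation_sets(list(setA = g$variants$snp_id[1:3],
                               empty_set = character(0)),
                          c(setA = "G1", empty_set = "G2"))
  outdir <- withr::local_tempdir()
  paths <- write_fixture_bundle(outdir, g$genotypes, g$variants, ph, ss,
                                sets = sets, or_scale = TRUE)

  back <- read_genotypes(paths$vcf)
  expect_identical(unname(back$genotypes), unname(g$genotypes))
  expect_identical(back$variants$snp_id, g$variants$snp_id)
  expect_identical(back$variants$counted_allele, g$variants$counted_allele)

  # an OR-scale file comes back as beta = log(OR)
  ss_back <- read_sumstats(paths$sumstats)
  expect_equal(ss_back$beta, ss$beta, tolerance = 1e-12)

  pheno_back <- utils::read.table(paths$phenotype, header = TRUE, sep = "\t")
  expect_identical(as.integer(pheno_back$status), unname(as.integer(ph)))

  bed <- read_bed_sets(paths$bed)
  sets_back <- snps_in_sets(g$variants, bed = bed,
                            groups = read_set_groups(paths$set_groups))
  expect_setequal(sets_back$sets$setA, sets$sets$setA)
  # the empty set survives the round trip as an empty set
  expect_identical(sets_back$sets$empty_set, character(0))
  expect_identical(unname(sets_back$groups["empty_set"]), "G2")
})
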