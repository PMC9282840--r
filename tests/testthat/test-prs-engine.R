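# LD, clumping, scoring and the threshold scan.

test_that("pairwise_r2 matches squared correlation and its edge cases", {
  set.seed(1)
  g <- rbinom(50, 2, 0.4)
  expect_equal(pairwise_r2(g, g), 1)
  expect_equal(pairwise_r2(g, 2 - g), 1)
  big1 <- rbinom(10000, 2, 0.3)
  big2 <- rbinom(10000, 2, 0.3)
  expect_lt(pairwise_r2(big1, big2), 0.01)
  expect_error(pairwise_r2(g, rep(1, 50)), "variance")
  expect_error(pairwise_r2(g, g[-1]), "length")
})

test_that("greedy clumping follows the p-ordered absorption rule", {
  # single SNP clumps to itself
  ss1 <- toy_sumstats("only", p = 0.3)
  g1 <- toy_geno(40, "only")
  cl1 <- greedy_clump(ss1, g1)
  expect_identical(cl1$index_snps, "only")
  expect_identical(cl1$members$only, character(0))

  # two SNPs in perfect LD 10 kb apart: smaller p wins
  set.seed(5)
  g <- toy_geno(60, c("lead", "tag"))
  g[, "tag"] <- g[, "lead"]
  ss <- toy_sumstats(c("lead", "tag"), pos = c(50000, 60000),
                     p = c(1e-8, 1e-4))
  cl <- greedy_clump(ss, g)
  expect_identical(cl$index_snps, "lead")
  expect_identical(cl$members$lead, "tag")

  # beyond the window the same pair stays independent
  ss_far <- toy_sumstats(c("lead", "tag"), pos = c(50000, 650000),
                         p = c(1e-8, 1e-4))
  cl_far <- greedy_clump(ss_far, g)
  expect_setequal(cl_far$index_snps, c("lead", "tag"))
})

test_that("clumping equals the re-scanning oracle on random instances", {
  set.seed(17)
  for (rep in 1:25) {
    inst <- random_clump_instance(sample(4:12, 1))
    got <- greedy_clump(inst$ss, inst$geno)
    want <- oracle_clump(inst$ss, inst$geno)
    expect_identical(got$index_snps, want$index_snps)
    expect_identical(got$members, want$members)
  }
})

test_that("clump output is invariant to input row order", {
  set.seed(29)
  inst <- random_clump_instance(10)
  shuffled <- inst$ss[sample(nrow(inst$ss)), , drop = FALSE]
  a <- greedy_clump(inst$ss, inst$geno)
  b <- greedy_clump(shuffled, inst$geno)
  expect_identical(a$index_snps, b$index_snps)
  expect_identical(a$members, b$members)
})

test_that("PRS scoring follows the per-individual averaging formula", {
  geno <- matrix(c(2L, 1L, 1L, NA), 2, 2,
                 dimnames = list(c("i1", "i2"), c("s1", "s2")))
  ss <- toy_sumstats(c("s1", "s2"), beta = c(0.5, -0.2))

  one <- score_prs(geno, ss, "s1")
  expect_equal(unname(one$scores["i1"]), 0.5 * 2 / (2 * 1))

  ss2 <- toy_sumstats(c("s1", "s2"), beta = c(0.1, -0.2))
  both <- score_prs(geno, ss2, c("s1", "s2"))
  expect_equal(unname(both$scores["i1"]), (0.1 * 2 - 0.2 * 1) / (2 * 2))
  # the missing genotype drops out of both numerator and M_j
  expect_equal(unname(both$scores["i2"]), (0.1 * 1) / (2 * 1))

  per_snp <- score_prs(geno, ss2, c("s1", "s2"), mj_mode = "snps")
  expect_equal(unname(per_snp$scores["i1"]), (0.1 * 2 - 0.2 * 1) / 2)

  expect_error(score_prs(geno, ss2, character(0)), "empty")
  expect_error(score_prs(geno, ss2, "nope"), "absent")
})

test_that("scoring is linear in beta and matches the loop oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n_snp <- sample(3:8, 1)
    ids <- sprintf("v%02d", seq_len(n_snp))
    geno <- toy_geno(30, ids, missing_rate = 0.15)
    geno[1, ] <- NA  # an all-missing individual gets an NA score
    ss <- toy_sumstats(ids, beta = rnorm(n_snp))
    got <- score_prs(geno, ss, ids)
    expect_equal(got$scores, oracle_prs(geno, ss, ids), tolerance = 1e-12)
    doubled <- ss
    doubled$beta <- 2 * ss$beta
    expect_equal(score_prs(geno, doubled, ids)$scores, 2 * got$scores,
                 tolerance = 1e-12)
  }
})

test_that("the default threshold ladder runs 5e-8 to 5e-1 then 1", {
  expect_identical(default_ladder(),
                   c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4, 5e-3, 5e-2, 5e-1, 1))
  fine <- default_ladder(fine = TRUE)
  expect_true(all(default_ladder() %in% fine))
  expect_true(all(diff(fine) > 0))
  expect_true(any(abs(fine - 0.769) < 1e-12))  # dense grid reaches 0.769
})

test_that("threshold scan marks the smallest-p row best with sane n_snps", {
  set.seed(41)
  spec <- ld_block_spec(1, 120, 0, c(0.2, 0.4))
  g <- simulate_ld_genotypes(600, spec, seed = 42)
  arch <- planted_architecture(
    list(list(snps = g$variants$snp_id[1:30], disease_effect = 0.05,
              longevity_effect = -0.3)), gwas_n = 30000)
  ph <- simulate_phenotype(g$genotypes, arch, seed = 43)
  ss <- simulate_sumstats(g$genotypes, g$variants, arch, seed = 44)
  clump <- greedy_clump(ss, g$genotypes)
  scan <- threshold_scan(ss, g$genotypes, ph, clump)
  tbl <- scan$table
  expect_identical(sum(tbl$best), 1L)
  expect_equal(tbl$p[tbl$best], min(tbl$p, na.rm = TRUE))
  ok <- !is.na(tbl$n_snps) & tbl$n_snps > 0
  expect_false(is.unsorted(tbl$n_snps[ok]))
  expect_identical(sort(scan$best_snps),
                   sort(intersect(clump$index_snps, scan$best_snps)))
  expect_error(threshold_scan(ss, g$genotypes, rep(1, 600), clump),
               "constant")
  expect_error(threshold_scan(ss, g$genotypes, ph, clump, ladder = c(0.5, 0.1)),
               "ascending")
})

test_that("tied best p-values resolve to the smaller threshold", {
  set.seed(51)
  g <- toy_geno(300, "a")
  ss <- toy_sumstats("a", p = 1e-9)
  ph <- stats::setNames(rbinom(300, 1, 0.5), rownames(g))
  clump <- greedy_clump(ss, g)
  # every ladder rung includes the same single SNP, so all nine fits (and
  # their p-values) tie exactly; the smallest threshold must win
  scan <- threshold_scan(ss, g, ph, clump)
  expect_true(all(scan$table$n_snps == 1))
  expect_equal(length(unique(scan$table$p)), 1)
  expect_identical(which(scan$table$best), 1L)
  expect_equal(scan$best_threshold, 5e-8)
})

test_that("clump members never enter the scores of their index", {
  set.seed(61)
  g <- toy_geno(100, c("idx", "mem"))
  g[, "mem"] <- g[, "idx"]
  ss <- toy_sumstats(c("idx", "mem"), pos = c(1000, 2000),
                     beta = c(0.4, 9.9), p = c(1e-6, 1e-3))
  clump <- greedy_clump(ss, g)
  expect_identical(clump$index_snps, "idx")
  prs_idx <- score_prs(g, ss, clump$index_snps)
  prs_solo <- score_prs(g[, "idx", drop = FALSE], ss, "idx")
  expect_identical(prs_idx$scores, prs_solo$scores)
})
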