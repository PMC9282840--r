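# Annotation sets, p-value bins, region masking and LD-block detection.

test_that("BED interval membership uses 0-based half-open coordinates", {
  variants <- toy_variants(c("v100", "v101"), pos = c(100, 101))
  bed <- data.frame(chrom = "1", start = 99, end = 100, name = "setX")
  sets <- snps_in_sets(variants, bed = bed)
  expect_identical(sets$sets$setX, "v100")

  # overlapping sets keep the SNP in both
  bed2 <- rbind(bed, data.frame(chrom = "1", start = 50, end = 150,
                                name = "setY"))
  sets2 <- snps_in_sets(variants, bed = bed2)
  expect_true("v100" %in% sets2$sets$setX)
  expect_true("v100" %in% sets2$sets$setY)

  expect_warning(
    snps_in_sets(variants,
                 bed = data.frame(chrom = "chrZ", start = 1, end = 10,
                                  name = "setZ")),
    "unknown chromosome")
  expect_error(
    snps_in_sets(variants,
                 bed = data.frame(chrom = "1", start = 10, end = 5,
                                  name = "bad")),
    "start > end")

  # id lists are taken verbatim (intersected with the variant table)
  sets3 <- snps_in_sets(variants, id_lists = list(manual = c("v101", "zz")))
  expect_identical(sets3$sets$manual, "v101")
})

test_that("group-level sets are the unions of their member sets", {
  s <- annotation_sets(list(a = c("x", "y"), b = c("y", "z"), c = "w"),
                       groups = c(a = "G1", b = "G1", c = "G2"))
  g <- group_snp_sets(s)
  expect_setequal(g$sets$G1, c("x", "y", "z"))
  expect_setequal(g$sets$G2, "w")
  expect_error(group_snp_sets(annotation_sets(list(a = "x"))), "group")
  expect_error(annotation_sets(list(a = "x"), groups = c(zz = "G")),
               "unknown sets")
})

test_that("p-value bins partition SNPs below the top cutpoint", {
  cut <- default_bin_cutpoints()
  expect_length(cut, 8)
  set.seed(13)
  p <- c(1e-9, 0.03, 10^runif(60, -9, -0.5))
  bin <- findInterval(p, cut, left.open = TRUE) + 1L
  expect_identical(bin[1], 1L)
  expect_identical(bin[2], 8L)
  inside <- bin <= 8
  expect_identical(sort(unique(p[inside])), sort(p[p <= 0.05]))
  # disjoint by construction: each p lands in exactly one interval
  for (b in unique(bin[inside]))
    expect_true(all(p[bin == b] > c(0, cut)[b] & p[bin == b] <= cut[b]))
})

test_that("bin scan drops SNPs above the last cutpoint and skips empty bins", {
  set.seed(14)
  ids <- sprintf("b%02d", 1:30)
  g <- toy_geno(250, ids)
  ph <- stats::setNames(rbinom(250, 1, 0.5), rownames(g))
  ss <- toy_sumstats(ids, pos = (1:30) * 800000,
                     p = c(rep(1e-9, 10), rep(0.02, 10), rep(0.5, 10)),
                     beta = 0.1)
  suppressMessages(tbl <- pvalue_bin_prs_scan(ss, g, ph))
  expect_setequal(tbl$bin, c(1L, 8L))  # 0.02 lands in (1e-2, 5e-2]
  expect_identical(tbl$n_snps[tbl$bin == 1], 10L)
  expect_identical(sum(tbl$n_snps), 20L)  # p = 0.5 SNPs excluded entirely
})

test_that("a single all-SNP set reproduces the genome-wide PRS exactly", {
  set.seed(15)
  spec <- ld_block_spec(2, 20, 0.6, c(0.2, 0.4))
  g <- simulate_ld_genotypes(300, spec, seed = 16)
  arch <- planted_architecture(
    list(list(snps = g$variants$snp_id[1:10], disease_effect = 0.1,
              longevity_effect = -0.2)), gwas_n = 10000)
  ph <- simulate_phenotype(g$genotypes, arch, seed = 17)
  ss <- simulate_sumstats(g$genotypes, g$variants, arch, seed = 18)

  all_set <- annotation_sets(list(everything = g$variants$snp_id))
  tbl <- set_prs_scan(ss, g$genotypes, ph, all_set)

  clump <- greedy_clump(ss, g$genotypes)
  scan <- threshold_scan(ss, g$genotypes, ph, clump, ladder = 1)
  expect_equal(tbl$coefficient, scan$table$coefficient, tolerance = 1e-12)
  expect_equal(tbl$p, scan$table$p, tolerance = 1e-12)
  expect_identical(tbl$n_snps, scan$table$n_snps)
  expect_identical(attr(tbl, "family_size"), 1L)
})

test_that("set scan skips sets with no target SNPs and keeps the family", {
  set.seed(19)
  ids <- sprintf("s%02d", 1:12)
  g <- toy_geno(200, ids)
  ph <- stats::setNames(rbinom(200, 1, 0.5), rownames(g))
  ss <- toy_sumstats(ids, pos = (1:12) * 700000, beta = 0.05, p = 0.01)
  sets <- annotation_sets(list(real = ids[1:6], ghost = "nowhere"))
  expect_message(tbl <- set_prs_scan(ss, g, ph, sets, n_traits = 16),
                 "skipped")
  expect_identical(tbl$label, "real")
  expect_identical(attr(tbl, "family_size"), 16L)
  expect_true(tbl$fdr_p >= tbl$p)
})

test_that("region masking is inclusive at both endpoints", {
  ss <- toy_sumstats(c("in1", "edge_lo", "edge_hi", "out", "other_chr"),
                     chrom = c("19", "19", "19", "19", "18"),
                     pos = c(45400000, 45361224, 45436657, 45300000,
                             45400000))
  suppressMessages(out <- mask_region(ss, apoe_region()))
  expect_setequal(out$snp_id, c("out", "other_chr"))
  expect_identical(attr(out, "n_masked"), 3L)
  # downstream scans can never see a masked SNP
  expect_length(intersect(out$snp_id, c("in1", "edge_lo", "edge_hi")), 0)
  r <- apoe_region()
  expect_identical(r$chrom, "19")
  expect_identical(r$start, 45361224L)
  expect_identical(r$end, 45436657L)
})

test_that("D-prime CI detects complete LD and its absence", {
  set.seed(23)
  pair <- complete_ld_pair(400)
  ci <- dprime_ci(pair[, 1], pair[, 2])
  expect_gte(ci$ci_high, 0.98)
  expect_gte(ci$ci_low, 0.7)
  expect_gt(ci$dprime, 0.9)

  ind <- cbind(rbinom(400, 2, 0.4), rbinom(400, 2, 0.4))
  ci2 <- dprime_ci(ind[, 1], ind[, 2])
  expect_lt(ci2$ci_high, 0.9)
  expect_error(dprime_ci(rep(0, 10), rbinom(10, 2, 0.5)), "monomorphic")
})

test_that("LD blocks: complete-LD pairs form one block, noise forms none", {
  set.seed(24)
  pair <- complete_ld_pair(500)
  geno <- cbind(pair, extra = rbinom(500, 2, 0.3))
  colnames(geno) <- c("p1", "p2", "p3")
  v <- toy_variants(c("p1", "p2", "p3"), pos = c(1000, 2000, 3000))
  blocks <- detect_ld_blocks(geno, v)
  expect_identical(nrow(blocks), 1L)
  expect_identical(blocks$first_snp, "p1")
  expect_identical(blocks$last_snp, "p2")

  noise <- sapply(1:4, function(i) rbinom(500, 2, 0.4))
  colnames(noise) <- sprintf("n%d", 1:4)
  vn <- toy_variants(colnames(noise), pos = (1:4) * 1000)
  expect_identical(nrow(detect_ld_blocks(noise, vn)), 0L)

  expect_identical(nrow(detect_ld_blocks(noise[, 1, drop = FALSE],
                                         vn[1, ])), 0L)
})

test_that("block detection equals the exhaustive-span oracle", {
  set.seed(25)
  for (rep in 1:3) {
    b1 <- complete_ld_pair(300)
    b2 <- complete_ld_pair(300, p1 = 0.4)
    geno <- cbind(b1, rbinom(300, 2, 0.35), b2)
    colnames(geno) <- sprintf("m%d", 1:5)
    v <- toy_variants(colnames(geno), pos = (1:5) * 5000)
    got <- detect_ld_blocks(geno, v)
    want <- oracle_ld_blocks(geno, v)
    expect_equal(got$start, as.numeric(want$start))
    expect_equal(got$end, as.numeric(want$end))
  }
})

test_that("window restriction selects the analysis region", {
  set.seed(26)
  pair <- complete_ld_pair(300)
  geno <- cbind(pair, far = rbinom(300, 2, 0.3))
  colnames(geno) <- c("w1", "w2", "w3")
  v <- toy_variants(colnames(geno), pos = c(1000, 2000, 99000))
  blocks <- detect_ld_blocks(geno, v,
                             window = list(chrom = "1", start = 500,
                                           end = 5000))
  expect_identical(nrow(blocks), 1L)
  expect_identical(blocks$n_snps, 2L)
})
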