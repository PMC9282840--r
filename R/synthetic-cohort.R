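# Synthetic cohort generation: LD-blocked genotypes through a Gaussian
# copula, binary phenotypes from a liability-threshold model, and GWAS
# summary statistics simulated around planted per-allele effects.
# Everything is driven by an explicit seed so fixtures are reproducible
# bit for bit.

#' Describe the LD-block structure of a simulated genotype panel
#'
#' Blocks are stretches of adjacent SNPs whose latent liabilities follow an
#' AR(1) correlation structure; different blocks are independent and are
#' placed more than 500 kb apart so that a clumping window never spans two
#' blocks.
#'
#' @param n_snps_per_block Number of SNPs in each block (scalar or vector of
#'   length `n_blocks`).
#' @param n_blocks Number of blocks.
#' @param within_block_r Correlation between adjacent latent haplotype
#'   variables inside a block, in `[0, 1)`. Zero gives independent SNPs.
#' @param maf_range Length-2 numeric, the range `(0, 0.5]` from which each
#'   SNP's minor-allele frequency is drawn uniformly.
#' @return An object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(n_snps_per_block, n_blocks,
                          within_block_r = 0,
                          maf_range = c(0.05, 0.5)) {
  if (any(n_snps_per_block < 1) || n_blocks < 1)
    stop("block counts must be positive")
  n_snps_per_block <- rep_len(as.integer(n_snps_per_block), n_blocks)
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (within_block_r < 0 || within_block_r > 1)
    stop("within_block_r must lie in [0, 1]")
  if (within_block_r >= 1 && any(n_snps_per_block > 1))
    stop("within_block_r must be < 1 for multi-SNP blocks")
  structure(
    list(n_snps_per_block = n_snps_per_block,
         n_blocks = as.integer(n_blocks),
         within_block_r = within_block_r,
         maf_range = maf_range),
    class = "ld_block_spec")
}

#' Planted genetic architecture for a simulated trade-off cohort
#'
#' A stratum is a set of SNPs sharing one per-allele log-odds effect on the
#' simulated disease (driving the simulated GWAS summary statistics) and one
#' per-allele effect on the longevity liability. Strata must be disjoint; any
#' SNP not listed carries null effects.
#'
#' @param strata A list; each element is a list with components `snps`
#'   (character vector of SNP ids), `disease_effect` and `longevity_effect`
#'   (finite scalars, log-odds per counted allele).
#' @param gwas_n Sample size of the simulated base GWAS (>= 50).
#' @param prevalence Fraction of the cohort that becomes a case under the
#'   liability threshold, in `(0, 1)`. The default 0.5 mirrors a balanced
#'   centenarian/control design.
#' @return An object of class `planted_architecture`.
#' @export
planted_architecture <- function(strata, gwas_n, prevalence = 0.5) {
  if (!is.list(strata)) stop("strata must be a list")
  all_snps <- character(0)
  for (s in strata) {
    if (!all(c("snps", "disease_effect", "longevity_effect") %in% names(s)))
      stop("each stratum needs snps, disease_effect and longevity_effect")
    if (!all(is.finite(c(s$disease_effect, s$longevity_effect))))
      stop("stratum effects must be finite")
    if (any(s$snps %in% all_snps))
      stop("strata SNP sets must be disjoint")
    all_snps <- c(all_snps, s$snps)
  }
  if (gwas_n < 50) stop("gwas_n must be at least 50")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)")
  structure(
    list(strata = strata, gwas_n = gwas_n, prevalence = prevalence),
    class = "planted_architecture")
}

# Per-SNP effect vector (named by snp id) for one side of the architecture.
architecture_effects <- function(arch, side = c("disease", "longevity")) {
  side <- match.arg(side)
  field <- paste0(side, "_effect")
  out <- numeric(0)
  for (s in arch$strata) {
    v <- rep(s[[field]], length(s$snps))
    names(v) <- s$snps
    out <- c(out, v)
  }
  out
}

#' Simulate LD-blocked diploid genotypes
#'
#' Each haplotype is generated from a latent multivariate normal with AR(1)
#' correlation `within_block_r` inside each block, thresholded at the normal
#' quantile of the SNP's allele frequency; summing two independent haplotypes
#' yields genotypes in Hardy-Weinberg proportions with tunable adjacent-SNP
#' r-squared. Blocks are separated by 600 kb so a 500 kb clumping window
#' never bridges them.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param spec An [ld_block_spec()].
#' @param seed Integer seed; fixes every output bit-identically.
#' @param chrom Chromosome label used for all simulated SNPs.
#' @param palindromic If `FALSE` (default) REF/ALT pairs are drawn only from
#'   strand-unambiguous combinations so harmonization keeps every SNP.
#' @return A list with `genotypes` (individuals x SNPs dosage matrix of the
#'   ALT allele, no missingness) and `variants` (a variant table: `snp_id`,
#'   `chrom`, `pos`, `counted_allele`, `other_allele`, `maf`, `block`).
#' @export
simulate_ld_genotypes <- function(n_individuals, spec, seed,
                                  chrom = "1", palindromic = FALSE) {
  if (!inherits(spec, "ld_block_spec")) stop("spec must be an ld_block_spec")
  if (n_individuals < 2) stop("n_individuals must be at least 2")
  set.seed(seed)
  m <- sum(spec$n_snps_per_block)
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  r <- spec$within_block_r

  # one latent AR(1) draw per haplotype, thresholded to alleles
  draw_haplotypes <- function() {
    z <- matrix(NA_real_, n_individuals, m)
    col <- 1L
    for (b in seq_len(spec$n_blocks)) {
      k <- spec$n_snps_per_block[b]
      z[, col] <- stats::rnorm(n_individuals)
      if (k > 1) {
        for (j in seq_len(k - 1L)) {
          z[, col + j] <- r * z[, col + j - 1L] +
            sqrt(1 - r^2) * stats::rnorm(n_individuals)
        }
      }
      col <- col + k
    }
    # allele = 1 when the latent variable falls below the MAF quantile
    sweep(z, 2, stats::qnorm(maf), "<") * 1L
  }
  geno <- draw_haplotypes() + draw_haplotypes()

  # positions: 1 kb spacing within a block, 600 kb gaps between blocks
  pos <- integer(m)
  cur <- 10000L
  col <- 1L
  for (b in seq_len(spec$n_blocks)) {
    k <- spec$n_snps_per_block[b]
    pos[col:(col + k - 1L)] <- cur + 1000L * (seq_len(k) - 1L)
    cur <- pos[col + k - 1L] + 600000L
    col <- col + k
  }

  alleles <- draw_allele_pairs(m, palindromic)
  variants <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chrom = chrom,
    pos = pos,
    counted_allele = alleles$alt,
    other_allele = alleles$ref,
    maf = maf,
    block = rep(seq_len(spec$n_blocks), spec$n_snps_per_block),
    stringsAsFactors = FALSE)
  colnames(geno) <- variants$snp_id
  rownames(geno) <- sprintf("id%05d", seq_len(n_individuals))
  list(genotypes = geno, variants = variants)
}

draw_allele_pairs <- function(m, palindromic) {
  pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
  if (palindromic)
    pairs <- c(pairs, list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C")))
  idx <- sample.int(length(pairs), m, replace = TRUE)
  list(ref = vapply(pairs[idx], `[`, "", 1L),
       alt = vapply(pairs[idx], `[`, "", 2L))
}

#' Simulate a binary longevity phenotype from a liability-threshold model
#'
#' Liability is the sum of planted longevity effects times genotype dosage
#' plus standard normal noise; individuals above the empirical
#' `1 - prevalence` liability quantile are cases, so the case fraction equals
#' the prevalence up to rounding. This mirrors a design that samples a fixed
#' number of long-lived cases and middle-aged controls rather than a
#' population cross-section.
#'
#' @param genotypes Individuals x SNPs dosage matrix with SNP-id columns.
#' @param arch A [planted_architecture()].
#' @param seed Integer seed.
#' @return Named integer vector of 0/1 status, one entry per individual.
#' @export
simulate_phenotype <- function(genotypes, arch, seed) {
  if (!inherits(arch, "planted_architecture"))
    stop("arch must be a planted_architecture")
  eff <- architecture_effects(arch, "longevity")
  missing_ids <- setdiff(names(eff), colnames(genotypes))
  if (length(missing_ids))
    stop("stratum SNPs absent from the genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  set.seed(seed)
  liability <- stats::rnorm(nrow(genotypes))
  if (length(eff)) {
    g <- genotypes[, names(eff), drop = FALSE]
    g[is.na(g)] <- 0  # a missing dosage contributes nothing to liability
    liability <- liability + as.vector(g %*% eff)
  }
  cut <- stats::quantile(liability, 1 - arch$prevalence, names = FALSE)
  status <- as.integer(liability > cut)
  names(status) <- rownames(genotypes)
  status
}

#' Simulate GWAS summary statistics around planted disease effects
#'
#' For each SNP the standard error is `1 / sqrt(2 * gwas_n * maf * (1 - maf))`
#' (the large-sample SE of a per-allele log-odds estimate), the estimated
#' beta is drawn normally around the planted disease effect with that SE, and
#' the p-value is the two-sided normal tail of `beta / se`. SNPs with larger
#' planted effects therefore reach stochastically smaller p-values, exactly
#' the gradient the p-value-bin analyses rely on.
#'
#' @param genotypes Dosage matrix (used only for its SNP ids / dimension).
#' @param variants Variant table with `snp_id`, `chrom`, `pos`, alleles, `maf`.
#' @param arch A [planted_architecture()]; `disease_effect` values are the
#'   planted means, `gwas_n` the base sample size.
#' @param seed Integer seed.
#' @param side Which planted effect to use as the mean: `"disease"` simulates
#'   the base-trait GWAS, `"longevity"` a companion longevity GWAS.
#' @return A harmonization-ready summary-statistics data frame with columns
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `p`, `n`.
#' @export
simulate_sumstats <- function(genotypes, variants, arch, seed,
                              side = c("disease", "longevity")) {
  side <- match.arg(side)
  if (!inherits(arch, "planted_architecture"))
    stop("arch must be a planted_architecture")
  if (any(variants$maf <= 0))
    stop("zero minor-allele frequency in variants")
  set.seed(seed)
  eff <- architecture_effects(arch, side)
  beta_true <- numeric(nrow(variants))
  names(beta_true) <- variants$snp_id
  hit <- intersect(names(eff), variants$snp_id)
  beta_true[hit] <- eff[hit]
  se <- 1 / sqrt(2 * arch$gwas_n * variants$maf * (1 - variants$maf))
  beta <- beta_true + stats::rnorm(nrow(variants), 0, se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  p <- pmax(p, .Machine$double.xmin)
  data.frame(
    snp_id = variants$snp_id,
    chrom = variants$chrom,
    pos = variants$pos,
    effect_allele = variants$counted_allele,
    other_allele = variants$other_allele,
    beta = beta,
    se = se,
    p = p,
    n = arch$gwas_n,
    stringsAsFactors = FALSE)
}

#' Bidirectional p-value-gradient architecture
#'
#' Builds a planted architecture in which genome-wide-significant disease
#' SNPs harm longevity while sub-significant disease SNPs help it, the
#' pattern the p-value-bin dissection is designed to expose. Disease effects
#' are placed at fixed z-value targets so that, after simulation noise, every
#' significance bin from genome-wide significant down to nominal is
#' populated: three strong strata around z of 6.2-6.9 and four weak strata
#' around z of 2.1-2.9.
#'
#' @param variants Variant table from [simulate_ld_genotypes()].
#' @param gwas_n Base GWAS sample size used to convert z targets into
#'   per-allele log-odds.
#' @param strong_longevity,weak_longevity Longevity liability effects per
#'   allele for the strong and weak strata.
#' @param n_strong,n_weak SNP counts drawn into the strong and weak strata
#'   (split evenly over the per-stratum z targets).
#' @param prevalence Case fraction for [simulate_phenotype()].
#' @return A [planted_architecture()] whose strata are named
#'   `strong1..strong3` and `weak1..weak4`.
#' @export
tradeoff_architecture <- function(variants, gwas_n = 50000,
                                  strong_longevity = -0.3,
                                  weak_longevity = 0.15,
                                  n_strong = 510, n_weak = 960,
                                  prevalence = 0.5) {
  z_strong <- c(6.2, 6.5, 6.9)
  z_weak <- c(2.9, 2.65, 2.4, 2.1)
  if (n_strong + n_weak > nrow(variants))
    stop("not enough variants for the requested architecture")
  mean_maf <- mean(variants$maf)
  se0 <- 1 / sqrt(2 * gwas_n * mean_maf * (1 - mean_maf))
  ids <- variants$snp_id
  take <- function(k) {
    got <- ids[seq_len(k)]
    ids <<- ids[-seq_len(k)]
    got
  }
  strata <- list()
  per_strong <- diff(round(seq(0, n_strong, length.out = length(z_strong) + 1)))
  for (i in seq_along(z_strong)) {
    strata[[paste0("strong", i)]] <- list(
      snps = take(per_strong[i]),
      disease_effect = z_strong[i] * se0,
      longevity_effect = strong_longevity)
  }
  per_weak <- diff(round(seq(0, n_weak, length.out = length(z_weak) + 1)))
  for (i in seq_along(z_weak)) {
    strata[[paste0("weak", i)]] <- list(
      snps = take(per_weak[i]),
      disease_effect = z_weak[i] * se0,
      longevity_effect = weak_longevity)
  }
  planted_architecture(strata, gwas_n = gwas_n, prevalence = prevalence)
}

#' Annotation-set architecture with opposite longevity effect directions
#'
#' Plants two named annotation sets whose SNPs share a common (positive)
#' disease effect but opposite longevity effects, emulating a trait whose
#' cell-type components pull longevity in different directions (for example
#' an immune component helping and a renal component harming survival).
#'
#' @param variants Variant table.
#' @param gwas_n Base GWAS sample size.
#' @param set_size SNPs per annotation set.
#' @param longevity_effect Magnitude of the per-allele longevity effect; the
#'   first set gets `+longevity_effect`, the second `-longevity_effect`.
#' @param disease_z Planted z target for the shared disease effect.
#' @param set_names Names of the two sets.
#' @param groups Group labels for the two sets.
#' @return A list with `arch` (a [planted_architecture()]) and `sets` (an
#'   [annotation_sets()] mapping the two sets to their SNPs and groups).
#' @export
annotation_architecture <- function(variants, gwas_n = 50000, set_size = 60,
                                    longevity_effect = 0.15, disease_z = 4,
                                    set_names = c("immune", "kidney"),
                                    groups = c("Immune", "Kidney")) {
  if (2 * set_size > nrow(variants))
    stop("not enough variants for two annotation sets")
  mean_maf <- mean(variants$maf)
  se0 <- 1 / sqrt(2 * gwas_n * mean_maf * (1 - mean_maf))
  ids_a <- variants$snp_id[seq_len(set_size)]
  ids_b <- variants$snp_id[set_size + seq_len(set_size)]
  arch <- planted_architecture(
    list(
      list(snps = ids_a, disease_effect = disease_z * se0,
           longevity_effect = longevity_effect),
      list(snps = ids_b, disease_effect = disease_z * se0,
           longevity_effect = -longevity_effect)),
    gwas_n = gwas_n)
  sets <- stats::setNames(list(ids_a, ids_b), set_names)
  list(arch = arch,
       sets = annotation_sets(sets, stats::setNames(groups, set_names)))
}

#' Write a simulated cohort to disk as plain-text fixture files
#'
#' Writes a VCFv4.2 genotype file, tab-separated disease (and optionally
#' longevity) summary statistics, a two-column phenotype table, BED
#' annotation intervals with a set-to-group mapping, and a region file. All
#' files round-trip losslessly through the package readers.
#'
#' @param outdir Output directory (created if needed).
#' @param genotypes,variants Output of [simulate_ld_genotypes()].
#' @param phenotype Named 0/1 vector from [simulate_phenotype()].
#' @param sumstats Disease summary statistics data frame.
#' @param sumstats_longevity Optional longevity summary statistics.
#' @param sets Optional [annotation_sets()] written as BED + mapping.
#' @param regions Optional data frame (`chrom`, `start`, `end`) of 1-based
#'   inclusive regions.
#' @param or_scale If `TRUE`, write the sumstats effect column as an odds
#'   ratio (`OR = exp(beta)`) instead of a beta column.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_bundle <- function(outdir, genotypes, variants, phenotype,
                                 sumstats, sumstats_longevity = NULL,
                                 sets = NULL, regions = NULL,
                                 or_scale = FALSE) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  if (!identical(colnames(genotypes), variants$snp_id))
    stop("genotype columns and variant table disagree on SNP ids")
  paths <- list()

  paths$vcf <- file.path(outdir, "genotypes.vcf")
  write_vcf(paths$vcf, genotypes, variants)

  paths$sumstats <- file.path(outdir, "sumstats_disease.tsv")
  write_sumstats(paths$sumstats, sumstats, or_scale = or_scale)
  if (!is.null(sumstats_longevity)) {
    paths$sumstats_longevity <- file.path(outdir, "sumstats_longevity.tsv")
    write_sumstats(paths$sumstats_longevity, sumstats_longevity,
                   or_scale = or_scale)
  }

  paths$phenotype <- file.path(outdir, "phenotype.tsv")
  utils::write.table(
    data.frame(id = names(phenotype), status = as.integer(phenotype)),
    paths$phenotype, sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(sets)) {
    paths$bed <- file.path(outdir, "annotations.bed")
    paths$set_groups <- file.path(outdir, "set_groups.tsv")
    write_annotation_bed(paths$bed, paths$set_groups, sets, variants)
  }
  if (!is.null(regions)) {
    paths$regions <- file.path(outdir, "regions.tsv")
    utils::write.table(regions, paths$regions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

write_vcf <- function(path, genotypes, variants) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=longprs synthetic cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(variants))) {
    g <- genotypes[, i]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(variants$chrom[i], variants$pos[i], variants$snp_id[i],
                       variants$other_allele[i], variants$counted_allele[i],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

write_sumstats <- function(path, ss, or_scale = FALSE) {
  out <- data.frame(SNP = ss$snp_id, CHR = ss$chrom, BP = ss$pos,
                    A1 = ss$effect_allele, A2 = ss$other_allele,
                    stringsAsFactors = FALSE)
  if (or_scale) out$OR <- exp(ss$beta) else out$BETA <- ss$beta
  out$SE <- ss$se
  out$P <- ss$p
  if (!is.null(ss$n)) out$N <- ss$n
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Each annotation set becomes one BED interval per member SNP
# (0-based half-open around the SNP position), name column = set name.
write_annotation_bed <- function(bed_path, map_path, sets, variants) {
  rows <- list()
  for (set_name in names(sets$sets)) {
    ids <- sets$sets[[set_name]]
    idx <- match(ids, variants$snp_id)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      # an empty set still appears in the mapping file
      next
    }
    rows[[set_name]] <- data.frame(
      chrom = variants$chrom[idx],
      start = variants$pos[idx] - 1L,
      end = variants$pos[idx],
      name = set_name, stringsAsFactors = FALSE)
  }
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  groups <- sets$groups
  if (is.null(groups))
    groups <- stats::setNames(rep(NA_character_, length(sets$sets)),
                              names(sets$sets))
  utils::write.table(
    data.frame(set = names(sets$sets),
               group = unname(groups[names(sets$sets)])),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}
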