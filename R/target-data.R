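# Target-cohort input: VCF genotype reading and the SNP-level QC filters
# applied before PRS construction (missingness, MAF, exact HWE in controls).

#' Read hard-call genotypes from a VCF file
#'
#' Keeps biallelic SNPs only: multi-allelic records and records whose REF or
#' ALT is not a single base are excluded (the count is reported via a
#' message and an attribute). The counted allele is ALT, so dosages are ALT
#' allele counts in `{0, 1, 2}`; missing genotypes (`./.`) become `NA`.
#'
#' @param vcf_path Path to a VCFv4.2 file with a GT field.
#' @return A list with `genotypes` (individuals x SNPs integer matrix),
#'   `variants` (variant table with `snp_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`, `maf` folded to `[0, 0.5]`) and
#'   `n_excluded` (records dropped as multi-allelic / non-SNP).
#' @export
read_genotypes <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", vcf_path)

  bases <- c("A", "C", "G", "T")
  keep <- toupper(fix$REF) %in% bases & toupper(fix$ALT) %in% bases
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(n_excluded, " multi-allelic or non-SNP record(s) excluded")
  if (!any(keep)) stop("no biallelic SNPs left after filtering records")

  ids <- fix$ID[keep]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[keep][no_id], ":", fix$POS[keep][no_id])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate SNP ids in VCF: ", paste(utils::head(dup, 10), collapse = ", "))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dosage <- codes[gsub("|", "/", gt, fixed = TRUE)]
  geno <- matrix(dosage, nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE,
                 dimnames = list(colnames(gt), ids))

  af <- colMeans(geno, na.rm = TRUE) / 2
  variants <- data.frame(
    snp_id = ids,
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    counted_allele = toupper(fix$ALT[keep]),
    other_allele = toupper(fix$REF[keep]),
    maf = pmin(af, 1 - af),
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  structure(list(genotypes = geno, variants = variants,
                 n_excluded = n_excluded))
}

#' SNP-level quality-control filter
#'
#' Removes SNPs with a high missing-genotype rate, low minor-allele
#' frequency, or Hardy-Weinberg exact-test p at or below `hwe_p_min`. All
#' three filters are evaluated on the input matrix and the union of failures
#' is removed, so the surviving SNP set does not depend on filter order. HWE
#' is tested in controls only when a status vector is supplied, since case
#' enrichment at truly associated SNPs distorts genotype proportions.
#'
#' @param geno Individuals x SNPs dosage matrix.
#' @param status Optional named 0/1 phenotype vector; HWE uses `status == 0`.
#' @param max_missing Maximum tolerated per-SNP missing fraction.
#' @param min_maf Minimum minor-allele frequency (monomorphic SNPs always fail).
#' @param hwe_p_min SNPs with exact HWE p `<=` this value are removed.
#' @param max_sample_missing Optional per-individual missingness cutoff;
#'   `NULL` (default) skips sample filtering.
#' @return A list with `genotypes` (filtered matrix), `report` (data frame of
#'   per-filter removal counts) and `removed` (named list of SNP ids per
#'   filter).
#' @export
snp_qc_filter <- function(geno, status = NULL, max_missing = 0.05,
                          min_maf = 0.01, hwe_p_min = 1e-5,
                          max_sample_missing = NULL) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1, hwe_p_min >= 0, hwe_p_min <= 1)
  if (!is.null(max_sample_missing)) {
    samp_miss <- rowMeans(is.na(geno))
    geno <- geno[samp_miss <= max_sample_missing, , drop = FALSE]
    if (!is.null(status)) status <- status[rownames(geno)]
  }
  miss <- colMeans(is.na(geno))
  af <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0

  hwe_geno <- geno
  if (!is.null(status)) {
    ctrl <- names(status)[status == 0]
    ctrl <- intersect(ctrl, rownames(geno))
    if (length(ctrl) == 0) stop("no controls available for the HWE test")
    hwe_geno <- geno[ctrl, , drop = FALSE]
  }
  hwe_p <- apply(hwe_geno, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })

  fail_miss <- miss > max_missing
  fail_maf <- maf < min_maf
  fail_hwe <- hwe_p <= hwe_p_min
  fail_any <- fail_miss | fail_maf | fail_hwe
  if (all(fail_any)) {
    counts <- c(missingness = sum(fail_miss), maf = sum(fail_maf),
                hwe = sum(fail_hwe))
    stop("no SNPs survive QC; binding filter: ",
         names(counts)[which.max(counts)])
  }
  report <- data.frame(
    filter = c("missingness", "maf", "hwe", "any"),
    threshold = c(max_missing, min_maf, hwe_p_min, NA),
    n_removed = c(sum(fail_miss), sum(fail_maf), sum(fail_hwe),
                  sum(fail_any)),
    stringsAsFactors = FALSE)
  list(genotypes = geno[, !fail_any, drop = FALSE],
       report = report,
       removed = list(missingness = colnames(geno)[fail_miss],
                      maf = colnames(geno)[fail_maf],
                      hwe = colnames(geno)[fail_hwe]))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts (of matching parity) that
#' are no more probable than the observed count. No mid-p correction is
#' applied. Symmetric in the two homozygote counts; returns values in
#' `(0, 1]`.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total >= 1).
#' @return Exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n < 1) stop("at least one individual is required")
  n_a <- 2 * n_hom_alt + n_het          # minor-side allele count
  n_b <- 2 * n_hom_ref + n_het
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = k | allele counts) up to a constant:
  #   k*log(2) - lfactorial((na-k)/2) - lfactorial(k) - lfactorial((nb-k)/2)
  lp <- hets * log(2) -
    lfactorial((n_a - hets) / 2) -
    lfactorial(hets) -
    lfactorial((n_b - hets) / 2)
  lp <- lp - max(lp)
  prob <- exp(lp) / sum(exp(lp))
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count has impossible parity")
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}
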