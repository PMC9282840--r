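# Stratified PRSs: annotation-set (cell-type / cell-type-group) and
# p-value-bin partitions, region masking, and D-prime confidence-interval
# LD-block detection.

#' Construct an annotation-set object
#'
#' @param sets Named list mapping set name to a character vector of SNP ids.
#' @param groups Optional named character vector mapping set name to group
#'   name; every named set must exist in `sets`.
#' @return An object of class `annotation_sets`.
#' @export
annotation_sets <- function(sets, groups = NULL) {
  if (!is.list(sets) ||
      (length(sets) && (is.null(names(sets)) || any(names(sets) == ""))))
    stop("sets must be a named list of SNP-id vectors")
  if (!is.null(groups)) {
    bad <- setdiff(names(groups), names(sets))
    if (length(bad))
      stop("groups reference unknown sets: ", paste(bad, collapse = ", "))
  }
  structure(list(sets = sets, groups = groups), class = "annotation_sets")
}

#' Union SNP sets at the group level
#'
#' @param sets An [annotation_sets()] with a group mapping.
#' @return An `annotation_sets` whose sets are the per-group unions.
#' @export
group_snp_sets <- function(sets) {
  if (is.null(sets$groups)) stop("no group mapping available")
  out <- list()
  for (set_name in names(sets$groups)) {
    g <- sets$groups[[set_name]]
    out[[g]] <- union(out[[g]], sets$sets[[set_name]])
  }
  annotation_sets(out)
}

#' Assign SNPs to annotation sets from BED intervals or id lists
#'
#' BED intervals are 0-based half-open; a SNP at 1-based position `pos`
#' falls in interval `[start, end)` when `start < pos <= end`. Sets may
#' overlap (annotations are not exclusive). Intervals on chromosomes absent
#' from the variant table are skipped with a warning.
#'
#' @param variants Variant table (`snp_id`, `chrom`, `pos`).
#' @param bed Optional data frame of intervals (`chrom`, `start`, `end`,
#'   `name`), e.g. from [read_bed_sets()].
#' @param id_lists Optional named list of SNP-id vectors taken verbatim.
#' @param groups Optional set-to-group mapping.
#' @return An [annotation_sets()] of SNP ids present in `variants`.
#' @export
snps_in_sets <- function(variants, bed = NULL, id_lists = NULL,
                         groups = NULL) {
  sets <- list()
  if (!is.null(bed)) {
    if (any(bed$start > bed$end)) stop("invalid BED interval: start > end")
    unknown <- setdiff(unique(bed$chrom), unique(variants$chrom))
    if (length(unknown)) {
      warning("skipping intervals on unknown chromosome(s): ",
              paste(unknown, collapse = ", "))
      bed <- bed[!bed$chrom %in% unknown, , drop = FALSE]
    }
    for (set_name in unique(bed$name)) {
      iv <- bed[bed$name == set_name, , drop = FALSE]
      hit <- rep(FALSE, nrow(variants))
      for (ch in unique(iv$chrom)) {
        on_ch <- variants$chrom == ch
        iv_ch <- iv[iv$chrom == ch, , drop = FALSE]
        pos <- variants$pos[on_ch]
        inside <- rep(FALSE, length(pos))
        for (k in seq_len(nrow(iv_ch)))
          inside <- inside | (pos > iv_ch$start[k] & pos <= iv_ch$end[k])
        hit[on_ch] <- hit[on_ch] | inside
      }
      sets[[set_name]] <- variants$snp_id[hit]
    }
  }
  if (!is.null(id_lists)) {
    for (set_name in names(id_lists))
      sets[[set_name]] <- intersect(id_lists[[set_name]], variants$snp_id)
  }
  # a set named in the group mapping but absent from the inputs (e.g. an
  # empty BED entry) is kept as an explicit empty set
  for (set_name in setdiff(names(groups), names(sets)))
    sets[[set_name]] <- character(0)
  annotation_sets(sets, groups)
}

#' Read BED intervals with a name column
#'
#' @param path BED file (chrom, start, end, name; 0-based half-open).
#' @return Data frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed_sets <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file needs chrom, start, end, name columns")
  bed <- bed[, 1:4]
  names(bed) <- c("chrom", "start", "end", "name")
  bed$chrom <- as.character(bed$chrom)
  bed
}

#' Read a set-to-group mapping file
#'
#' @param path Two-column tab-separated file (`set`, `group`) with header.
#' @return Named character vector mapping set to group.
#' @export
read_set_groups <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.character(m$group), m$set)
}

# Shared core: per labelled SNP set, clump within the set, score all
# surviving index SNPs, and regress on the phenotype.
scan_snp_partitions <- function(ss, geno, pheno, partitions,
                                r2_threshold = 0.1, window_bp = 500000,
                                covariates = NULL, mj_mode = "alleles") {
  rows <- list()
  for (label in names(partitions)) {
    snps <- intersect(partitions[[label]],
                      intersect(ss$snp_id, colnames(geno)))
    if (length(snps) == 0) {
      message("partition '", label, "' has no SNPs in the target; skipped")
      next
    }
    ss_sub <- ss[ss$snp_id %in% snps, , drop = FALSE]
    clump <- greedy_clump(ss_sub, geno, r2_threshold, window_bp)
    prs <- score_prs(geno, ss_sub, clump$index_snps, mj_mode = mj_mode)
    z <- standardize_scores(prs$scores)
    fit <- fit_logistic(pheno[rownames(geno)], z, covariates)
    rows[[label]] <- data.frame(
      label = label, n_snps = length(clump$index_snps),
      coefficient = fit$coefficient, se = fit$se, p = fit$p,
      pseudo_r2 = nagelkerke_r2(fit$ll_null, fit$ll_full, fit$n),
      direction = ifelse(fit$coefficient >= 0, "positive", "negative"),
      stringsAsFactors = FALSE)
    rows[[label]]$.scores <- I(list(prs$scores))
  }
  rows
}

finalize_partition_scan <- function(rows, n_traits, alpha) {
  if (length(rows) == 0) stop("every partition was empty")
  scores <- lapply(rows, function(r) r$.scores[[1]])
  tbl <- do.call(rbind, lapply(rows, function(r) r[, 1:7]))
  rownames(tbl) <- NULL
  m_total <- as.integer(nrow(tbl) * n_traits)
  tbl$fdr_p <- bh_fdr_family(tbl$p, m_total)
  tbl$bonferroni_sig <- tbl$p < bonferroni_threshold(alpha, m_total)
  attr(tbl, "scores") <- scores
  attr(tbl, "family_size") <- m_total
  tbl
}

#' Annotation-set stratified PRS scan
#'
#' For each annotation set (or group-level union), restricts the summary
#' statistics to the set's SNPs, clumps within the set, scores a PRS on all
#' surviving index SNPs (threshold p <= `p_threshold`, default 1 so every
#' set SNP is eligible), and fits a logistic model of longevity status on
#' the standardized set PRS. FDR adjustment uses a family of
#' `n_sets * n_traits` tests, with a Bonferroni flag at the same family
#' size.
#'
#' @param ss Harmonized summary statistics.
#' @param geno Dosage matrix.
#' @param pheno Named 0/1 phenotype vector.
#' @param sets An [annotation_sets()].
#' @param level `"set"` scans each set; `"group"` scans per-group unions.
#' @param p_threshold Base-study p cutoff applied before clumping.
#' @param n_traits Number of traits in the correction family (default 1).
#' @param alpha Significance level for the Bonferroni flag.
#' @param r2_threshold,window_bp,covariates,mj_mode Clumping / scoring
#'   parameters as in [greedy_clump()] and [score_prs()].
#' @return Data frame with one row per non-empty set: `label`, `n_snps`,
#'   `coefficient`, `se`, `p`, `pseudo_r2`, `direction`, `fdr_p`,
#'   `bonferroni_sig`; per-set score vectors in `attr(, "scores")`.
#' @export
set_prs_scan <- function(ss, geno, pheno, sets, level = c("set", "group"),
                         p_threshold = 1, n_traits = 1, alpha = 0.05,
                         r2_threshold = 0.1, window_bp = 500000,
                         covariates = NULL, mj_mode = "alleles") {
  level <- match.arg(level)
  if (!inherits(sets, "annotation_sets"))
    stop("sets must be an annotation_sets object")
  if (length(sets$sets) == 0) stop("no annotation sets supplied")
  if (level == "group") sets <- group_snp_sets(sets)
  ss_use <- ss[ss$p <= p_threshold, , drop = FALSE]
  rows <- scan_snp_partitions(ss_use, geno, pheno, sets$sets,
                              r2_threshold, window_bp, covariates, mj_mode)
  finalize_partition_scan(rows, n_traits, alpha)
}

#' Default p-value-bin cutpoints
#'
#' Eight thresholds spanning genome-wide significance to nominal:
#' 5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 5e-2.
#'
#' @return Ascending numeric vector of 8 cutpoints (defining 8 bins).
#' @export
default_bin_cutpoints <- function() {
  c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 5e-2)
}

#' P-value-bin stratified PRS scan
#'
#' Partitions SNPs into significance bins `(0, c1], (c1, c2], ...,
#' (c_{k-1}, c_k]` by their base-study p-value (SNPs with `p > c_k` are
#' excluded entirely), then clumps, scores and regresses each bin's PRS as
#' in [set_prs_scan()]. The bins are pairwise disjoint and their union is
#' the set of SNPs with `p <=` the largest cutpoint.
#'
#' @inheritParams set_prs_scan
#' @param cutpoints Ascending bin boundaries (default
#'   [default_bin_cutpoints()]).
#' @return As [set_prs_scan()], with one row per non-empty bin and an
#'   integer `bin` column.
#' @export
pvalue_bin_prs_scan <- function(ss, geno, pheno,
                                cutpoints = default_bin_cutpoints(),
                                n_traits = 1, alpha = 0.05,
                                r2_threshold = 0.1, window_bp = 500000,
                                covariates = NULL, mj_mode = "alleles") {
  if (is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be strictly ascending")
  bin_of <- findInterval(ss$p, cutpoints, left.open = TRUE) + 1L
  labels <- paste0("bin", seq_along(cutpoints))
  partitions <- lapply(seq_along(cutpoints), function(b)
    ss$snp_id[bin_of == b])
  names(partitions) <- labels
  rows <- scan_snp_partitions(ss, geno, pheno, partitions,
                              r2_threshold, window_bp, covariates, mj_mode)
  tbl <- finalize_partition_scan(rows, n_traits, alpha)
  tbl$bin <- match(tbl$label, labels)
  tbl
}

#' Remove a genomic region from summary statistics
#'
#' Drops every row whose position falls inside the region (1-based,
#' endpoints inclusive) on the matching chromosome; the removal count is
#' reported via a message and an attribute.
#'
#' @param ss Summary-statistics data frame with `chrom` and `pos`.
#' @param region List or one-row data frame with `chrom`, `start`, `end`.
#' @return The filtered table with attribute `n_masked`.
#' @export
mask_region <- function(ss, region) {
  if (region$start > region$end) stop("invalid region: start > end")
  inside <- ss$chrom == region$chrom &
    ss$pos >= region$start & ss$pos <= region$end
  message(sum(inside), " SNP(s) masked in ", region$chrom, ":",
          region$start, "-", region$end)
  out <- ss[!inside, , drop = FALSE]
  attr(out, "n_masked") <- sum(inside)
  out
}

#' The APOE region used for masking
#'
#' chr19:45,361,224-45,436,657 (GRCh37), the union of the LD blocks around
#' APOE observed in Han Chinese and 1000 Genomes East Asian genotypes.
#'
#' @param chrom Chromosome label to use (default `"19"`).
#' @return List with `chrom`, `start`, `end`.
#' @export
apoe_region <- function(chrom = "19") {
  list(chrom = chrom, start = 45361224L, end = 45436657L)
}

#' D-prime point estimate and likelihood-based confidence interval
#'
#' For two biallelic loci with unphased hard-call genotypes, computes the
#' normalized disequilibrium |D'| by maximum likelihood over a grid, and a
#' 90% confidence interval as the 5th and 95th percentiles of the
#' grid-normalized likelihood (the construction used by confidence-interval
#' block-finding methods). The sign of D is resolved from the composite
#' genotype covariance so the grid runs over non-negative D'.
#'
#' @param g1,g2 Genotype dosage vectors (missing entries pairwise-deleted).
#' @param grid_step Grid resolution on D' (default 0.005).
#' @return List with `dprime`, `ci_low`, `ci_high`.
#' @export
dprime_ci <- function(g1, g2, grid_step = 0.005) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2) stop("fewer than two complete genotype pairs")
  p_a <- mean(g1) / 2
  p_b <- mean(g2) / 2
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1))
    stop("monomorphic locus; D' undefined")
  if (stats::cov(g1, g2) < 0) {  # recode locus 2 so D >= 0
    g2 <- 2 - g2
    p_b <- 1 - p_b
  }
  d_max <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  dp_grid <- seq(0, 1, by = grid_step)
  ll <- vapply(dp_grid, function(dp) {
    d <- dp * d_max
    h11 <- p_a * p_b + d
    h10 <- p_a * (1 - p_b) - d
    h01 <- (1 - p_a) * p_b - d
    h00 <- (1 - p_a) * (1 - p_b) + d
    h <- pmax(c(h00, h01, h10, h11), 1e-12)
    cellp <- matrix(c(
      h[1]^2,        2 * h[1] * h[2],                h[2]^2,
      2 * h[1] * h[3], 2 * (h[4] * h[1] + h[3] * h[2]), 2 * h[2] * h[4],
      h[3]^2,        2 * h[3] * h[4],                h[4]^2),
      nrow = 3, byrow = TRUE)
    sum(tab * log(pmax(cellp, 1e-300)))
  }, 0)
  lik <- exp(ll - max(ll))
  post <- cumsum(lik) / sum(lik)
  list(dprime = dp_grid[which.max(ll)],
       ci_low = dp_grid[which(post >= 0.05)[1]],
       ci_high = dp_grid[which(post >= 0.95)[1]])
}

#' Detect LD blocks with the D-prime confidence-interval rule
#'
#' A SNP pair is in strong LD when its D' CI has lower bound `>= 0.70` and
#' upper bound `>= 0.98`; it shows strong recombination when the upper bound
#' is `< 0.90`; either way the pair is informative. A candidate span of SNPs
#' is a block when it has at least one informative pair and at least
#' `min_strong_frac` of its informative pairs are strong. Maximal
#' non-overlapping qualifying spans are reported, longest first
#' (deterministic; ties go to the leftmost span).
#'
#' @param geno Dosage matrix.
#' @param variants Variant table for the matrix columns.
#' @param window Optional region (`chrom`, `start`, `end`) restricting the
#'   analysis.
#' @param lower_strong,upper_strong CI bounds defining strong LD.
#' @param upper_recomb CI upper bound below which a pair shows strong
#'   recombination.
#' @param min_strong_frac Minimum fraction of informative pairs in strong LD.
#' @return Data frame of blocks (`chrom`, `start`, `end`, `n_snps`,
#'   `first_snp`, `last_snp`), zero rows when fewer than 2 SNPs are in the
#'   window or no span qualifies.
#' @export
detect_ld_blocks <- function(geno, variants, window = NULL,
                             lower_strong = 0.70, upper_strong = 0.98,
                             upper_recomb = 0.90, min_strong_frac = 0.95) {
  v <- variants
  if (!is.null(window)) {
    v <- v[v$chrom == window$chrom & v$pos >= window$start &
             v$pos <= window$end, , drop = FALSE]
  }
  v <- v[order(v$pos), , drop = FALSE]
  m <- nrow(v)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      first_snp = character(0), last_snp = character(0))
  if (m < 2) return(empty)

  # classify every pair: 1 = strong LD, -1 = strong recombination, 0 = other
  pair_class <- matrix(0L, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ci <- tryCatch(dprime_ci(geno[, v$snp_id[i]], geno[, v$snp_id[j]]),
                     error = function(e) NULL)
      if (is.null(ci)) next
      if (ci$ci_low >= lower_strong && ci$ci_high >= upper_strong)
        pair_class[i, j] <- 1L
      else if (ci$ci_high < upper_recomb)
        pair_class[i, j] <- -1L
    }
  }
  span_ok <- function(i, j) {
    cls <- pair_class[i:j, i:j][upper.tri(diag(j - i + 1))]
    informative <- sum(cls != 0L)
    informative >= 1 && sum(cls == 1L) / informative >= min_strong_frac
  }
  spans <- expand.grid(i = seq_len(m), j = seq_len(m))
  spans <- spans[spans$j > spans$i, , drop = FALSE]
  spans <- spans[order(-(spans$j - spans$i), spans$i), , drop = FALSE]
  taken <- rep(FALSE, m)
  blocks <- list()
  for (k in seq_len(nrow(spans))) {
    i <- spans$i[k]; j <- spans$j[k]
    if (any(taken[i:j])) next
    if (span_ok(i, j)) {
      taken[i:j] <- TRUE
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom = v$chrom[i], start = v$pos[i], end = v$pos[j],
        n_snps = j - i + 1L, first_snp = v$snp_id[i],
        last_snp = v$snp_id[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks)) return(empty)
  out <- do.call(rbind, blocks)
  out[order(out$start), , drop = FALSE]
}
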