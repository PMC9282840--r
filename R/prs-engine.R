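# PRS engine: pairwise LD, greedy p-value-ordered clumping, per-individual
# scoring, and the p-value threshold scan that defines a trait's best PRS.

#' Squared Pearson correlation between two genotype vectors
#'
#' Missing entries are pairwise-deleted before the correlation is computed.
#'
#' @param g1,g2 Equal-length genotype dosage vectors.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("fewer than two complete pairs")
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0)
    stop("zero genotype variance after pairwise deletion")
  stats::cor(g1[ok], g2[ok])^2
}

#' Greedy LD clumping by ascending p-value
#'
#' SNPs are visited in order of ascending p-value (ties broken by chromosome
#' then position, making the result independent of input row order). Each
#' not-yet-assigned SNP becomes an index SNP and absorbs every unassigned
#' SNP on the same chromosome within `window_bp` of it whose r-squared with
#' the index exceeds `r2_threshold`.
#'
#' @param ss Harmonized summary statistics (`snp_id`, `chrom`, `pos`, `p`).
#' @param geno Dosage matrix whose columns cover the SNPs in `ss`; LD is
#'   computed from these target genotypes.
#' @param r2_threshold SNPs with r-squared above this are clumped (default
#'   0.1).
#' @param window_bp Window half-width in base pairs around the index SNP
#'   (default 500 kb).
#' @return An object of class `clump_result`: `index_snps` (ordered ids),
#'   `members` (named list mapping index to absorbed ids), `r2_threshold`,
#'   `window_bp`.
#' @export
greedy_clump <- function(ss, geno, r2_threshold = 0.1, window_bp = 500000) {
  ss <- ss[ss$snp_id %in% colnames(geno), , drop = FALSE]
  if (nrow(ss) == 0) stop("no overlap between summary statistics and genotypes")
  ord <- order(ss$p, ss$chrom, ss$pos)
  ss <- ss[ord, , drop = FALSE]

  assigned <- rep(FALSE, nrow(ss))
  index_snps <- character(0)
  members <- list()
  for (i in seq_len(nrow(ss))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    id <- ss$snp_id[i]
    index_snps <- c(index_snps, id)
    cand <- which(!assigned &
                    ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= window_bp)
    absorbed <- character(0)
    if (length(cand)) {
      g0 <- geno[, id]
      r2 <- suppressWarnings(
        stats::cor(g0, geno[, ss$snp_id[cand], drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      hit <- !is.na(r2) & r2 > r2_threshold
      absorbed <- ss$snp_id[cand][hit]
      assigned[cand[hit]] <- TRUE
    }
    members[[id]] <- absorbed
  }
  structure(list(index_snps = index_snps, members = members,
                 r2_threshold = r2_threshold, window_bp = window_bp),
            class = "clump_result")
}

#' Score a polygenic risk score
#'
#' For individual `j`, `PRS_j = sum_i(beta_i * G_ij) / M_j` over the SNPs in
#' `snp_set` with a non-missing genotype. With `mj_mode = "alleles"`
#' (default) `M_j` is twice the individual's non-missing SNP count, counting
#' both chromosomes; `"snps"` divides by the SNP count instead. The scale
#' factor cancels in downstream regression p-values. Individuals with no
#' non-missing SNP get an `NA` score.
#'
#' @param geno Individuals x SNPs dosage matrix.
#' @param ss Harmonized summary statistics supplying `beta` per SNP.
#' @param snp_set Character vector of SNP ids to include.
#' @param mj_mode `"alleles"` or `"snps"`.
#' @return An object of class `prs_result`: `scores` (named per-individual
#'   vector), `n_snps`, `snp_ids`, `threshold` (NA here; set by scan
#'   functions).
#' @export
score_prs <- function(geno, ss, snp_set, mj_mode = c("alleles", "snps")) {
  mj_mode <- match.arg(mj_mode)
  snp_set <- unique(snp_set)
  if (length(snp_set) == 0) stop("snp_set is empty")
  unknown <- setdiff(snp_set, intersect(ss$snp_id, colnames(geno)))
  if (length(unknown))
    stop("snp_set contains SNPs absent from the harmonized data: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  beta <- ss$beta[match(snp_set, ss$snp_id)]
  g <- geno[, snp_set, drop = FALSE]
  present <- !is.na(g)
  g0 <- g
  g0[!present] <- 0
  num <- as.vector(g0 %*% beta)
  m <- rowSums(present) * if (mj_mode == "alleles") 2 else 1
  scores <- ifelse(m > 0, num / m, NA_real_)
  names(scores) <- rownames(geno)
  structure(list(scores = scores, n_snps = length(snp_set),
                 snp_ids = snp_set, threshold = NA_real_),
            class = "prs_result")
}

#' Default p-value threshold ladder
#'
#' From genome-wide significance upward by an order of magnitude per step,
#' with the endpoint 1 appended: 5e-8, 5e-7, ..., 5e-1, 1. `fine = TRUE`
#' additionally inserts a dense grid in steps of 5e-5, emulating a
#' fine-grained threshold search.
#'
#' @param fine Add the dense grid (default `FALSE`).
#' @return Ascending numeric vector of thresholds.
#' @export
default_ladder <- function(fine = FALSE) {
  base <- c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4, 5e-3, 5e-2, 5e-1, 1)
  if (fine) base <- sort(unique(c(base, seq(5e-5, 1, by = 5e-5))))
  base
}

#' Threshold scan: best-PRS selection over a p-value ladder
#'
#' For each cutoff, the PRS is scored on clump index SNPs with base-study
#' `p <=` cutoff, standardized, and regressed on the binary phenotype with
#' logistic regression; the row with the smallest association p-value is the
#' best PRS (ties go to the smaller threshold). Cutoffs with no eligible
#' SNPs produce a skipped row.
#'
#' @param ss Harmonized summary statistics.
#' @param geno Dosage matrix.
#' @param phenotype Named 0/1 vector aligned to `rownames(geno)`.
#' @param clump A [greedy_clump()] result; only index SNPs enter scores.
#' @param ladder Ascending p-value cutoffs (default [default_ladder()]).
#' @param covariates Optional numeric covariate matrix.
#' @param mj_mode Passed to [score_prs()].
#' @return An object of class `scan_result`: `table` (one row per threshold:
#'   `threshold`, `n_snps`, `coefficient`, `se`, `p`, `pseudo_r2`, `best`),
#'   `best_threshold`, `best_snps`, `best_scores`.
#' @export
threshold_scan <- function(ss, geno, phenotype, clump,
                           ladder = default_ladder(), covariates = NULL,
                           mj_mode = "alleles") {
  if (length(ladder) == 0 || is.unsorted(ladder, strictly = TRUE))
    stop("ladder must be non-empty and strictly ascending")
  phenotype <- phenotype[rownames(geno)]
  if (length(unique(stats::na.omit(phenotype))) < 2)
    stop("phenotype is constant")
  idx_p <- ss$p[match(clump$index_snps, ss$snp_id)]

  rows <- vector("list", length(ladder))
  best_scores <- NULL
  best_snps <- NULL
  for (k in seq_along(ladder)) {
    snps <- clump$index_snps[!is.na(idx_p) & idx_p <= ladder[k]]
    if (length(snps) == 0) {
      rows[[k]] <- data.frame(threshold = ladder[k], n_snps = 0L,
                              coefficient = NA_real_, se = NA_real_,
                              p = NA_real_, pseudo_r2 = NA_real_)
      next
    }
    prs <- score_prs(geno, ss, snps, mj_mode = mj_mode)
    z <- standardize_scores(prs$scores)
    fit <- fit_logistic(phenotype, z, covariates)
    rows[[k]] <- data.frame(
      threshold = ladder[k], n_snps = length(snps),
      coefficient = fit$coefficient, se = fit$se, p = fit$p,
      pseudo_r2 = nagelkerke_r2(fit$ll_null, fit$ll_full, fit$n))
    rows[[k]]$.scores <- I(list(prs$scores))
    rows[[k]]$.snps <- I(list(snps))
  }
  tbl <- do.call(rbind, lapply(rows, function(r)
    r[, c("threshold", "n_snps", "coefficient", "se", "p", "pseudo_r2")]))
  tbl$best <- FALSE
  ok <- which(!is.na(tbl$p))
  if (length(ok) == 0) stop("every threshold produced an empty SNP set")
  best_k <- ok[which.min(tbl$p[ok])]  # which.min returns the first minimum,
  tbl$best[best_k] <- TRUE            # i.e. the smallest tied threshold
  best_scores <- rows[[best_k]]$.scores[[1]]
  best_snps <- rows[[best_k]]$.snps[[1]]
  structure(list(table = tbl, best_threshold = tbl$threshold[best_k],
                 best_snps = best_snps, best_scores = best_scores),
            class = "scan_result")
}

standardize_scores <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

#' @export
print.scan_result <- function(x, ...) {
  cat("PRS threshold scan (", nrow(x$table), " thresholds)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("best threshold:", format(x$best_threshold), "with",
      length(x$best_snps), "SNPs\n")
  invisible(x)
}
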