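# Pleiotropy dissection: classify SNPs by effect-direction concordance
# between a disease and longevity, annotate nearest genes, and build an
# odds-ratio lookup table for a list of longevity SNPs.

#' Classify pleiotropic SNPs into concordant / discordant panels
#'
#' Starting from the SNPs used in the disease's best PRS, keeps those with
#' nominal significance (`p < alpha`) in both the disease and the longevity
#' summary statistics, with the longevity beta expressed on the disease risk
#' allele. Panel 1 collects SNPs whose risk allele also increases the chance
#' of longevity (`beta_longevity > 0`); panel 2 those whose risk allele
#' reduces it (`beta_longevity < 0`).
#'
#' @param best_prs_snps Character vector of SNP ids (the disease's best-PRS
#'   SNP set).
#' @param ss_disease Risk-oriented disease summary statistics (all
#'   `beta >= 0`; run [orient_to_risk()] first).
#' @param ss_longevity Longevity summary statistics harmonized to the same
#'   target; rows whose alleles are swapped relative to the disease table
#'   are re-expressed on the disease risk allele, and irreconcilable allele
#'   pairs raise an error naming the SNP.
#' @param alpha Nominal significance cutoff (default 0.05).
#' @return A `panel_table` data frame: `snp_id`, `beta_disease`,
#'   `beta_longevity`, `p_disease`, `p_longevity`, `panel`.
#' @export
select_pleiotropic <- function(best_prs_snps, ss_disease, ss_longevity,
                               alpha = 0.05) {
  if (any(ss_disease$beta < 0, na.rm = TRUE))
    stop("disease summary statistics are not risk-oriented; ",
         "apply orient_to_risk() first")
  shared <- intersect(best_prs_snps,
                      intersect(ss_disease$snp_id, ss_longevity$snp_id))
  di <- match(shared, ss_disease$snp_id)
  li <- match(shared, ss_longevity$snp_id)

  beta_long <- ss_longevity$beta[li]
  same <- ss_longevity$effect_allele[li] == ss_disease$effect_allele[di] &
    ss_longevity$other_allele[li] == ss_disease$other_allele[di]
  swapped <- ss_longevity$effect_allele[li] == ss_disease$other_allele[di] &
    ss_longevity$other_allele[li] == ss_disease$effect_allele[di]
  bad <- !same & !swapped
  if (any(bad))
    stop("allele mismatch between disease and longevity tables for SNP: ",
         paste(utils::head(shared[bad], 5), collapse = ", "))
  beta_long[swapped] <- -beta_long[swapped]

  keep <- ss_disease$p[di] < alpha & ss_longevity$p[li] < alpha
  out <- data.frame(
    snp_id = shared[keep],
    beta_disease = ss_disease$beta[di][keep],
    beta_longevity = beta_long[keep],
    p_disease = ss_disease$p[di][keep],
    p_longevity = ss_longevity$p[li][keep],
    stringsAsFactors = FALSE)
  zero <- out$beta_longevity == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with exactly zero longevity effect dropped")
    out <- out[!zero, , drop = FALSE]
  }
  out$panel <- ifelse(out$beta_longevity > 0, "panel1", "panel2")
  rownames(out) <- NULL
  class(out) <- c("panel_table", "data.frame")
  out
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates; GFF3 input keeps `gene` features only and takes the gene
#' name from the `Name=` (falling back to `ID=`) attribute.
#'
#' @param path Path ending in `.bed` or `.gff`/`.gff3`.
#' @return Data frame with `chrom`, `start`, `end`, `name` (1-based
#'   inclusive).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
    g <- g[g[[3]] == "gene", , drop = FALSE]
    name <- sub(".*Name=([^;]+).*", "\\1", g[[9]])
    no_name <- !grepl("Name=", g[[9]])
    name[no_name] <- sub(".*ID=([^;]+).*", "\\1", g[[9]][no_name])
    data.frame(chrom = as.character(g[[1]]), start = as.integer(g[[4]]),
               end = as.integer(g[[5]]), name = name,
               stringsAsFactors = FALSE)
  } else {
    g <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(g) < 4) stop("gene BED needs chrom, start, end, name columns")
    data.frame(chrom = as.character(g[[1]]), start = as.integer(g[[2]]) + 1L,
               end = as.integer(g[[3]]), name = as.character(g[[4]]),
               stringsAsFactors = FALSE)
  }
}

#' Label SNPs with their nearest gene(s)
#'
#' A SNP inside a gene gets that gene's name (distance 0). Otherwise the
#' nearest gene upstream and the nearest gene downstream are both reported
#' as `"NAME(dist = D)"` with the base-pair distance, joined by a comma.
#' SNPs on a chromosome with no genes are labelled `"intergenic"`.
#'
#' @param snps Variant-table subset (`snp_id`, `chrom`, `pos`).
#' @param genes Gene interval table from [read_genes()] (1-based inclusive).
#' @return Character vector of labels, named by SNP id.
#' @export
annotate_nearest_genes <- function(snps, genes) {
  labels <- vapply(seq_len(nrow(snps)), function(i) {
    ch <- snps$chrom[i]; pos <- snps$pos[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) return("intergenic")
    inside <- g$start <= pos & pos <= g$end
    if (any(inside))
      return(paste(unique(g$name[inside]), collapse = ", "))
    parts <- character(0)
    left <- g[g$end < pos, , drop = FALSE]
    if (nrow(left)) {
      k <- which.min(pos - left$end)
      parts <- c(parts, sprintf("%s(dist = %s)", left$name[k],
                                format(pos - left$end[k], big.mark = ",",
                                       scientific = FALSE, trim = TRUE)))
    }
    right <- g[g$start > pos, , drop = FALSE]
    if (nrow(right)) {
      k <- which.min(right$start - pos)
      parts <- c(parts, sprintf("%s(dist = %s)", right$name[k],
                                format(right$start[k] - pos, big.mark = ",",
                                       scientific = FALSE, trim = TRUE)))
    }
    if (!length(parts)) "intergenic" else paste(parts, collapse = ", ")
  }, "")
  names(labels) <- snps$snp_id
  labels
}

#' Odds-ratio lookup for a list of SNPs in two GWAS
#'
#' For each SNP, reports the disease and longevity odds ratio
#' (`OR = exp(beta)`), 95% confidence interval
#' (`exp(beta +/- 1.959964 * se)`), p-value, and a nominal-significance flag
#' at `p < alpha` in both studies. SNPs missing from either table produce a
#' row of `NA`s with a warning.
#'
#' @param snp_list Character vector of SNP ids.
#' @param ss_disease,ss_longevity Summary statistics with `beta`, `se`, `p`.
#' @param alpha Nominal significance level (default 0.05).
#' @param genes Optional gene table; adds a `gene_label` column via
#'   [annotate_nearest_genes()] (requires `chrom`/`pos` in `ss_disease`).
#' @return Data frame with one row per requested SNP.
#' @export
effect_lookup <- function(snp_list, ss_disease, ss_longevity, alpha = 0.05,
                          genes = NULL) {
  zcrit <- 1.959964
  one_side <- function(ss, ids) {
    i <- match(ids, ss$snp_id)
    data.frame(or = exp(ss$beta[i]),
               ci_low = exp(ss$beta[i] - zcrit * ss$se[i]),
               ci_high = exp(ss$beta[i] + zcrit * ss$se[i]),
               p = ss$p[i])
  }
  dis <- one_side(ss_disease, snp_list)
  lon <- one_side(ss_longevity, snp_list)
  miss <- is.na(dis$or) | is.na(lon$or)
  if (any(miss))
    warning(sum(miss), " SNP(s) missing from one of the tables")
  out <- data.frame(
    snp_id = snp_list,
    counted_allele = ss_disease$effect_allele[match(snp_list,
                                                    ss_disease$snp_id)],
    or_disease = dis$or, ci_low_disease = dis$ci_low,
    ci_high_disease = dis$ci_high, p_disease = dis$p,
    or_longevity = lon$or, ci_low_longevity = lon$ci_low,
    ci_high_longevity = lon$ci_high, p_longevity = lon$p,
    both_significant = !miss & dis$p < alpha & lon$p < alpha,
    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    snp_pos <- ss_disease[match(snp_list, ss_disease$snp_id),
                          c("snp_id", "chrom", "pos")]
    out$gene_label <- unname(annotate_nearest_genes(snp_pos, genes))
  }
  out
}

#' Export panel gene lists for external enrichment tools
#'
#' Writes one plain-text gene list per panel, suitable as input to a GO
#' enrichment web service.
#'
#' @param panel A `panel_table` from [select_pleiotropic()] with a
#'   `gene_label` column (add one via [annotate_nearest_genes()]).
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_panel_genes <- function(panel, outdir) {
  if (is.null(panel$gene_label))
    stop("panel table has no gene_label column")
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  for (pn in c("panel1", "panel2")) {
    genes <- panel$gene_label[panel$panel == pn]
    genes <- unique(unlist(strsplit(gsub("\\(dist = [0-9,]+\\)", "", genes),
                                    ", ")))
    genes <- setdiff(trimws(genes), c("", "intergenic"))
    path <- file.path(outdir, paste0(pn, "_genes.txt"))
    writeLines(genes, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
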