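# GWAS summary-statistic input and harmonization against the target
# variant table: allele matching, effect-sign swaps, complementary-strand
# rescue, and exclusion of ambiguous palindromic SNPs.

#' Read GWAS summary statistics from delimited text
#'
#' Expects (possibly aliased) columns for SNP id, chromosome, position,
#' effect allele, other allele, effect size (`BETA` or `OR`), standard error
#' and p-value. An `OR` column is converted with [or_to_beta()]. Rows with a
#' missing p-value or missing alleles are dropped with a message; `p = 0` is
#' clamped to the smallest positive double with a warning.
#'
#' @param path Path to a tab- or whitespace-delimited file with a header.
#' @param column_map Optional named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `or`, `se`, `p`, `n`) to the file's column names; unmapped fields fall
#'   back to common aliases.
#' @return A summary-statistics data frame with canonical columns and beta
#'   on the log-odds scale.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) == 1)  # fall back to whitespace splitting
    raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
  aliases <- list(
    snp_id = c("SNP", "snp", "rsid", "RSID", "ID", "MarkerName"),
    chrom = c("CHR", "chr", "chrom", "CHROM", "chromosome"),
    pos = c("BP", "bp", "pos", "POS", "position", "base_pair_location"),
    effect_allele = c("A1", "a1", "effect_allele", "EA", "ALT"),
    other_allele = c("A2", "a2", "other_allele", "OA", "NEA", "REF"),
    beta = c("BETA", "beta", "b", "Effect"),
    or = c("OR", "or", "odds_ratio"),
    se = c("SE", "se", "StdErr", "standard_error"),
    p = c("P", "p", "pval", "PVAL", "p_value", "P-value"),
    n = c("N", "n", "sample_size"))
  pick <- function(field) {
    if (!is.null(column_map) && field %in% names(column_map)) {
      col <- column_map[[field]]
      if (!col %in% names(raw))
        stop("mapped column not present in file: ", col)
      return(col)
    }
    hit <- intersect(aliases[[field]], names(raw))
    if (length(hit)) hit[1] else NA_character_
  }
  cols <- vapply(names(aliases), pick, "")
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "p")
  missing_req <- required[is.na(cols[required])]
  if (length(missing_req))
    stop("unmappable header; missing columns for: ",
         paste(missing_req, collapse = ", "))
  if (is.na(cols["beta"]) && is.na(cols["or"]))
    stop("summary statistics must contain a BETA or an OR column")

  ss <- data.frame(
    snp_id = as.character(raw[[cols["snp_id"]]]),
    chrom = as.character(raw[[cols["chrom"]]]),
    pos = as.integer(raw[[cols["pos"]]]),
    effect_allele = toupper(as.character(raw[[cols["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[cols["other_allele"]]])),
    stringsAsFactors = FALSE)
  ss$beta <- if (!is.na(cols["beta"])) as.numeric(raw[[cols["beta"]]])
             else or_to_beta(as.numeric(raw[[cols["or"]]]))
  ss$se <- if (!is.na(cols["se"])) as.numeric(raw[[cols["se"]]]) else NA_real_
  ss$p <- as.numeric(raw[[cols["p"]]])
  ss$n <- if (!is.na(cols["n"])) as.numeric(raw[[cols["n"]]]) else NA_real_

  zero_p <- !is.na(ss$p) & ss$p == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " p-value(s) of 0 clamped to the smallest ",
            "positive double")
    ss$p[zero_p] <- .Machine$double.xmin
  }
  drop <- is.na(ss$p) | is.na(ss$effect_allele) | is.na(ss$other_allele) |
    ss$effect_allele == "" | ss$other_allele == ""
  if (any(drop))
    message(sum(drop), " row(s) dropped for missing p-value or alleles")
  ss[!drop, , drop = FALSE]
}

#' Convert an odds ratio to a log-odds effect size
#'
#' @param or_value Positive odds ratio(s).
#' @return `log(or_value)`.
#' @export
or_to_beta <- function(or_value) {
  if (any(!is.finite(or_value) | or_value <= 0))
    stop("odds ratios must be positive and finite")
  log(or_value)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics to a target variant table
#'
#' Aligns each base-study row to the target's counted/other alleles. Four
#' outcomes are possible: direct match (kept as is); swapped alleles (beta
#' negated and allele labels exchanged); complementary-strand match (both
#' alleles complemented, then the direct/swap rule applied); and exclusion
#' for palindromic (A/T, C/G) or irreconcilable allele pairs. Rows absent
#' from the target, and SNP ids that occur more than once in the base study,
#' are also excluded. The report partitions the input row count exactly.
#'
#' @param ss Summary-statistics data frame from [read_sumstats()] or
#'   [simulate_sumstats()].
#' @param target Variant table (`snp_id`, `chrom`, `pos`, `counted_allele`,
#'   `other_allele`).
#' @param keep_palindromic If `TRUE`, palindromic SNPs are retained when
#'   their alleles match directly or by swap (strand identity is then
#'   assumed); default `FALSE` excludes them as ambiguous.
#' @param join One of `"auto"`, `"snp_id"`, `"position"`. `"auto"` joins on
#'   SNP id when the tables share ids, otherwise on chromosome + position.
#' @return A list with `sumstats` (aligned rows; `effect_allele` equals the
#'   target's counted allele, `chrom`/`pos` taken from the target) and
#'   `report` (data frame of category counts).
#' @export
harmonize_alleles <- function(ss, target, keep_palindromic = FALSE,
                              join = c("auto", "snp_id", "position")) {
  join <- match.arg(join)
  n_input <- nrow(ss)
  category <- rep(NA_character_, n_input)

  dup_ids <- unique(ss$snp_id[duplicated(ss$snp_id)])
  category[ss$snp_id %in% dup_ids] <- "duplicate"

  if (join == "auto")
    join <- if (length(intersect(ss$snp_id, target$snp_id))) "snp_id"
            else "position"
  key_ss <- if (join == "snp_id") ss$snp_id else paste(ss$chrom, ss$pos)
  key_tg <- if (join == "snp_id") target$snp_id
            else paste(target$chrom, target$pos)
  idx <- match(key_ss, key_tg)
  category[is.na(idx) & is.na(category)] <- "not_in_target"

  open <- which(is.na(category))
  a1 <- ss$effect_allele[open]
  a2 <- ss$other_allele[open]
  tc <- target$counted_allele[idx[open]]
  to <- target$other_allele[idx[open]]

  pal <- is_palindromic(a1, a2)
  direct <- a1 == tc & a2 == to
  swap <- a1 == to & a2 == tc
  c1 <- unname(COMPLEMENT[a1])
  c2 <- unname(COMPLEMENT[a2])
  comp_direct <- !pal & !is.na(c1) & !is.na(c2) & c1 == tc & c2 == to
  comp_swap <- !pal & !is.na(c1) & !is.na(c2) & c1 == to & c2 == tc

  cat_open <- rep("mismatch", length(open))
  cat_open[comp_direct] <- "strand_matched"
  cat_open[comp_swap] <- "strand_flipped"
  cat_open[direct] <- "matched"
  cat_open[swap] <- "flipped"
  if (keep_palindromic) {
    cat_open[pal & !direct & !swap] <- "mismatch"
  } else {
    cat_open[pal] <- "palindromic"
  }
  category[open] <- cat_open

  keep_cats <- c("matched", "flipped", "strand_matched", "strand_flipped")
  kept <- which(category %in% keep_cats)
  out <- ss[kept, , drop = FALSE]
  ti <- idx[kept]
  negate <- category[kept] %in% c("flipped", "strand_flipped")
  out$beta <- ifelse(negate, -out$beta, out$beta)
  out$snp_id <- target$snp_id[ti]
  out$chrom <- target$chrom[ti]
  out$pos <- target$pos[ti]
  out$effect_allele <- target$counted_allele[ti]
  out$other_allele <- target$other_allele[ti]
  rownames(out) <- NULL

  levels_all <- c(keep_cats, "palindromic", "mismatch", "not_in_target",
                  "duplicate")
  report <- data.frame(
    category = levels_all,
    n = as.integer(table(factor(category, levels = levels_all))),
    stringsAsFactors = FALSE)
  stopifnot(sum(report$n) == n_input)
  list(sumstats = out, report = report)
}

#' Orient all effects to the risk allele
#'
#' Consolidates effect alleles into risk alleles: rows with a negative beta
#' have their allele labels swapped and the beta negated (the effect of one
#' allele is minus the effect of the other), leaving `|beta|`, `se` and `p`
#' unchanged. Idempotent.
#'
#' @param ss Harmonized summary-statistics data frame.
#' @return The table with all `beta >= 0`.
#' @export
orient_to_risk <- function(ss) {
  flip <- !is.na(ss$beta) & ss$beta < 0
  tmp <- ss$effect_allele[flip]
  ss$effect_allele[flip] <- ss$other_allele[flip]
  ss$other_allele[flip] <- tmp
  ss$beta[flip] <- -ss$beta[flip]
  ss
}
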