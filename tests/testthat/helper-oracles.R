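# Independent oracles and small fixture builders shared across tests.
# Every oracle is written from the definition, not by calling the package
# path it checks.

# Greedy clumping, re-derived from the definition: repeatedly take the
# lowest-p unassigned SNP as index and re-scan all remaining SNPs for
# window + r2 eligibility at every step.
oracle_clump <- function(ss, geno, r2_threshold = 0.1, window_bp = 500000) {
  ss <- ss[ss$snp_id %in% colnames(geno), , drop = FALSE]
  remaining <- ss[order(ss$p, ss$chrom, ss$pos), , drop = FALSE]
  index_snps <- character(0)
  members <- list()
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    index_snps <- c(index_snps, idx$snp_id)
    rest <- remaining[-1, , drop = FALSE]
    absorbed <- character(0)
    if (nrow(rest) > 0) {
      for (k in seq_len(nrow(rest))) {
        if (rest$chrom[k] == idx$chrom &&
            abs(rest$pos[k] - idx$pos) <= window_bp) {
          r2 <- suppressWarnings(
            stats::cor(geno[, idx$snp_id], geno[, rest$snp_id[k]],
                       use = "pairwise.complete.obs")^2)
          if (!is.na(r2) && r2 > r2_threshold)
            absorbed <- c(absorbed, rest$snp_id[k])
        }
      }
    }
    members[[idx$snp_id]] <- absorbed
    remaining <- rest[!rest$snp_id %in% absorbed, , drop = FALSE]
  }
  list(index_snps = index_snps, members = members)
}

# PRS from the formula with explicit loops over individuals and SNPs.
oracle_prs <- function(geno, ss, snp_set, per_allele = TRUE) {
  beta <- ss$beta[match(snp_set, ss$snp_id)]
  out <- rep(NA_real_, nrow(geno))
  for (j in seq_len(nrow(geno))) {
    num <- 0; m <- 0
    for (i in seq_along(snp_set)) {
      g <- geno[j, snp_set[i]]
      if (!is.na(g)) {
        num <- num + beta[i] * g
        m <- m + 1
      }
    }
    if (m > 0) out[j] <- num / (if (per_allele) 2 * m else m)
  }
  names(out) <- rownames(geno)
  out
}

# Benjamini-Hochberg from the step-up definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, m * p[ord[j]] / j), 0)
    adj_sorted[i] <- min(vals)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# HWE exact p by direct enumeration with exact (non-log) probabilities.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_bb + n_ab
  nb <- 2 * n_aa + n_ab
  if (na == 0 || nb == 0) return(1)
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  # P(k het | allele counts) = n! na! nb! 2^k /
  #                            ((na-k)/2)! k! ((nb-k)/2)! (2n)!
  prob <- vapply(hets, function(k) {
    exp(lfactorial(n) + lfactorial(na) + lfactorial(nb) + k * log(2) -
          lfactorial((na - k) / 2) - lfactorial(k) -
          lfactorial((nb - k) / 2) - lfactorial(2 * n))
  }, 0)
  prob <- prob / sum(prob)
  obs <- prob[hets == n_ab]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# Newton-Raphson logistic regression (intercept + one predictor), written
# against the score equations directly.
oracle_logistic <- function(y, x, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- X %*% b
    mu <- 1 / (1 + exp(-eta))
    W <- as.vector(mu * (1 - mu))
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- X %*% b
  mu <- 1 / (1 + exp(-eta))
  se <- sqrt(diag(solve(t(X) %*% (X * as.vector(mu * (1 - mu))))))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coefficient = unname(b[2]), se = unname(se[2]), ll = ll)
}

# Exhaustive LD-block finder applying the CI rule to every span.
oracle_ld_blocks <- function(geno, variants, lower_strong = 0.70,
                             upper_strong = 0.98, upper_recomb = 0.90,
                             min_strong_frac = 0.95) {
  v <- variants[order(variants$pos), , drop = FALSE]
  m <- nrow(v)
  classify <- function(i, j) {
    ci <- tryCatch(dprime_ci(geno[, v$snp_id[i]], geno[, v$snp_id[j]]),
                   error = function(e) NULL)
    if (is.null(ci)) return(0L)
    if (ci$ci_low >= lower_strong && ci$ci_high >= upper_strong) return(1L)
    if (ci$ci_high < upper_recomb) return(-1L)
    0L
  }
  qualifies <- function(i, j) {
    cls <- c()
    for (a in i:(j - 1)) for (b in (a + 1):j) cls <- c(cls, classify(a, b))
    inf <- sum(cls != 0)
    inf >= 1 && sum(cls == 1) / inf >= min_strong_frac
  }
  spans <- expand.grid(i = seq_len(m), j = seq_len(m))
  spans <- spans[spans$j > spans$i, , drop = FALSE]
  spans <- spans[order(-(spans$j - spans$i), spans$i), , drop = FALSE]
  taken <- rep(FALSE, m)
  blocks <- list()
  for (k in seq_len(nrow(spans))) {
    i <- spans$i[k]; j <- spans$j[k]
    if (any(taken[i:j]) || !qualifies(i, j)) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1]] <- c(start = v$pos[i], end = v$pos[j])
  }
  if (!length(blocks)) return(data.frame(start = integer(0), end = integer(0)))
  out <- as.data.frame(do.call(rbind, blocks))
  out[order(out$start), , drop = FALSE]
}

# ---- fixture builders -----------------------------------------------------

# A small sumstats data frame on one or more chromosomes.
toy_sumstats <- function(snp_id, chrom = "1", pos = seq_along(snp_id) * 1000,
                         a1 = "A", a2 = "G", beta = 0.1, se = 0.05,
                         p = 0.01) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = a1, other_allele = a2,
             beta = beta, se = se, p = p, n = 1000,
             stringsAsFactors = FALSE)
}

toy_variants <- function(snp_id, chrom = "1",
                         pos = seq_along(snp_id) * 1000,
                         counted = "A", other = "G", maf = 0.3) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             counted_allele = counted, other_allele = other, maf = maf,
             stringsAsFactors = FALSE)
}

# Random genotype matrix with independent binomial SNPs.
toy_geno <- function(n, snp_ids, maf = 0.3, missing_rate = 0) {
  g <- matrix(stats::rbinom(n * length(snp_ids), 2, maf), n,
              dimnames = list(sprintf("i%04d", seq_len(n)), snp_ids))
  if (missing_rate > 0)
    g[stats::runif(length(g)) < missing_rate] <- NA
  g
}

# Correlated multi-SNP instance for clumping tests: SNPs fall in loose
# position clusters, with some columns derived from others to create LD.
random_clump_instance <- function(n_snps, n_ind = 80) {
  ids <- sprintf("s%02d", seq_len(n_snps))
  chrom <- sample(c("1", "2"), n_snps, replace = TRUE)
  pos <- sample.int(2000000, n_snps)
  geno <- toy_geno(n_ind, ids, maf = stats::runif(1, 0.15, 0.45))
  # rewrite a random subset of columns as noisy copies of earlier columns
  for (k in seq_len(n_snps)) {
    if (k > 1 && stats::runif(1) < 0.5) {
      src <- sample.int(k - 1, 1)
      flip <- stats::runif(n_ind) < 0.15
      geno[, k] <- ifelse(flip, stats::rbinom(n_ind, 2, 0.3), geno[, src])
      chrom[k] <- chrom[src]
      pos[k] <- pos[src] + sample.int(800000, 1)
    }
  }
  ss <- toy_sumstats(ids, chrom = chrom, pos = pos,
                     p = stats::runif(n_snps))
  # guard against constant columns (oracle and implementation both skip
  # them via NA correlations, but keep instances well-behaved)
  for (k in seq_len(n_snps))
    if (stats::var(geno[, k]) == 0) geno[1:2, k] <- c(0, 2)
  list(ss = ss, geno = geno)
}

# Two-locus genotypes in complete LD (D' = 1): allele at locus 2 only ever
# appears on haplotypes carrying the allele at locus 1.
complete_ld_pair <- function(n, p1 = 0.5, frac = 0.8) {
  h1a <- stats::rbinom(n, 1, p1); h1b <- stats::rbinom(n, 1, p1)
  h2a <- h1a * stats::rbinom(n, 1, frac)
  h2b <- h1b * stats::rbinom(n, 1, frac)
  cbind(g1 = h1a + h1b, g2 = h2a + h2b)
}
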