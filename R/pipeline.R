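# Pipeline orchestration: validate a YAML configuration and run the
# simulate -> QC -> harmonize -> scan -> stratify -> dissect -> predict
# chain into a run directory with a reproducibility manifest.

STAGE_ORDER <- c("simulate", "qc", "harmonize", "scan", "bins", "stratify",
                 "mask", "dissect", "predict")

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, applies defaults, and reports every problem
#' at once rather than stopping at the first.
#'
#' @param path Path to a YAML configuration.
#' @return A list with `config` (normalized configuration) and `errors`
#'   (character vector; empty when the configuration is valid).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  if (is.null(cfg$schema_version)) note("missing key: schema_version")
  if (is.null(cfg$build)) note("missing key: build (declared genome build)")
  if (is.null(cfg$seed)) note("missing key: seed")
  else if (cfg$seed != round(cfg$seed)) note("seed must be an integer")

  par_defaults <- list(r2_threshold = 0.1, window_kb = 500, alpha = 0.05,
                       hwe_p_min = 1e-5, max_missing = 0.05, min_maf = 0.01,
                       cv_k = 5, cv_iterations = 3,
                       cv_families = "logistic")
  cfg$parameters <- utils::modifyList(par_defaults,
                                      as.list(cfg$parameters))
  p <- cfg$parameters
  if (p$r2_threshold <= 0 || p$r2_threshold >= 1)
    note("parameters.r2_threshold must lie in (0, 1)")
  if (p$window_kb <= 0) note("parameters.window_kb must be positive")
  if (p$alpha <= 0 || p$alpha >= 1)
    note("parameters.alpha must lie in (0, 1)")
  if (p$max_missing < 0 || p$max_missing > 1)
    note("parameters.max_missing must lie in [0, 1]")
  if (p$cv_k < 2) note("parameters.cv_k must be at least 2")
  unknown_fam <- setdiff(p$cv_families, names(default_model_grid()))
  if (length(unknown_fam))
    note(paste("unknown cv_families:", paste(unknown_fam, collapse = ", ")))

  if (is.null(cfg$simulate)) {
    required <- c("genotypes", "phenotype", "sumstats")
    for (key in required) {
      path_k <- cfg$paths[[key]]
      if (is.null(path_k)) note(paste0("missing key: paths.", key))
      else if (!file.exists(path_k))
        note(paste0("paths.", key, " does not exist: ", path_k))
    }
    for (key in setdiff(names(cfg$paths),
                        c(required, "sumstats_longevity", "annotations_bed",
                          "set_groups", "genes"))) {
      note(paste0("unknown key: paths.", key))
    }
    for (key in c("sumstats_longevity", "annotations_bed", "set_groups",
                  "genes")) {
      path_k <- cfg$paths[[key]]
      if (!is.null(path_k) && !file.exists(path_k))
        note(paste0("paths.", key, " does not exist: ", path_k))
    }
  }
  if (!is.null(cfg$mask_region)) {
    r <- cfg$mask_region
    if (is.null(r$chrom) || is.null(r$start) || is.null(r$end))
      note("mask_region needs chrom, start, end")
    else if (r$start > r$end) note("mask_region: start > end")
  }
  if (!is.null(cfg$stages)) {
    bad <- setdiff(cfg$stages, STAGE_ORDER)
    if (length(bad)) note(paste("unknown stages:", paste(bad, collapse = ", ")))
  }
  list(config = cfg, errors = errors)
}

write_stage_table <- function(tbl, out_dir, name, manifest, stage, params) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest[[length(manifest) + 1]] <- data.frame(
    stage = stage, output = basename(path),
    md5 = unname(tools::md5sum(path)), n_rows = nrow(tbl),
    params = params, stringsAsFactors = FALSE)
  manifest
}

#' Run the analysis pipeline from a validated configuration
#'
#' Executes the requested stages in dependency order, writing each stage's
#' table into `out_dir` together with a manifest recording output hashes,
#' row counts and parameters; re-running with an identical configuration and
#' seed reproduces every output bit for bit.
#'
#' @param config Normalized configuration from [validate_config()] (the
#'   `config` element), or a path to a YAML file.
#' @param stages Optional subset of stages to run (default: the config's
#'   `stages`, falling back to all applicable stages).
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results plus the
#'   manifest data frame.
#' @export
run_pipeline <- function(config, stages = NULL, out_dir = "longprs_run") {
  if (is.character(config)) {
    v <- validate_config(config)
    if (length(v$errors))
      stop("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "))
    config <- v$config
  }
  p <- config$parameters
  window_bp <- p$window_kb * 1000
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(stages)) stages <- config$stages
  if (is.null(stages)) stages <- STAGE_ORDER
  stages <- STAGE_ORDER[STAGE_ORDER %in% stages]
  manifest <- list()
  state <- new.env(parent = emptyenv())
  need <- function(what, from_stage) {
    if (!exists(what, envir = state))
      stop("stage depends on missing upstream output '", what,
           "'; run the '", from_stage, "' stage first")
    get(what, envir = state)
  }

  if ("simulate" %in% stages) {
    sim <- config$simulate
    if (is.null(sim)) stop("config has no simulate block")
    spec <- ld_block_spec(
      n_snps_per_block = sim$n_snps_per_block %||% 1,
      n_blocks = sim$n_blocks %||% 400,
      within_block_r = sim$within_block_r %||% 0,
      maf_range = unlist(sim$maf_range %||% c(0.2, 0.4)))
    g <- simulate_ld_genotypes(sim$n_individuals %||% 600, spec,
                               seed = config$seed)
    arch <- if (identical(sim$architecture, "annotation")) {
      aa <- annotation_architecture(g$variants, set_size = sim$set_size %||% 40)
      assign("sets", aa$sets, envir = state)
      aa$arch
    } else {
      tradeoff_architecture(g$variants,
                            n_strong = sim$n_strong %||% 120,
                            n_weak = sim$n_weak %||% 220)
    }
    pheno <- simulate_phenotype(g$genotypes, arch, seed = config$seed + 1)
    ss_dis <- simulate_sumstats(g$genotypes, g$variants, arch,
                                seed = config$seed + 2, side = "disease")
    ss_lon <- simulate_sumstats(g$genotypes, g$variants, arch,
                                seed = config$seed + 3, side = "longevity")
    sim_dir <- file.path(out_dir, "sim")
    paths <- write_fixture_bundle(
      sim_dir, g$genotypes, g$variants, pheno, ss_dis,
      sumstats_longevity = ss_lon,
      sets = if (exists("sets", envir = state)) get("sets", envir = state))
    config$paths <- utils::modifyList(
      as.list(config$paths),
      list(genotypes = paths$vcf, phenotype = paths$phenotype,
           sumstats = paths$sumstats,
           sumstats_longevity = paths$sumstats_longevity))
    manifest <- write_stage_table(g$variants, out_dir, "simulated_variants",
                                  manifest, "simulate",
                                  paste0("seed=", config$seed))
  }

  geno_path <- config$paths$genotypes
  if (any(c("qc", "harmonize", "scan", "bins", "stratify", "mask",
            "dissect", "predict") %in% stages)) {
    if (is.null(geno_path) || !file.exists(geno_path))
      stop("genotype file missing: ", geno_path %||% "<unset>")
    target <- read_genotypes(geno_path)
    assign("target", target, envir = state)
    pheno_tbl <- utils::read.table(config$paths$phenotype, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
    pheno <- stats::setNames(as.integer(pheno_tbl[[2]]),
                             as.character(pheno_tbl[[1]]))
    assign("pheno", pheno, envir = state)
  }

  if ("qc" %in% stages) {
    target <- need("target", "simulate")
    qc <- snp_qc_filter(target$genotypes, status = get("pheno", state),
                        max_missing = p$max_missing, min_maf = p$min_maf,
                        hwe_p_min = p$hwe_p_min)
    target$genotypes <- qc$genotypes
    target$variants <- target$variants[
      target$variants$snp_id %in% colnames(qc$genotypes), , drop = FALSE]
    assign("target", target, envir = state)
    manifest <- write_stage_table(qc$report, out_dir, "qc_report", manifest,
                                  "qc", sprintf("max_missing=%g,min_maf=%g,hwe=%g",
                                                p$max_missing, p$min_maf,
                                                p$hwe_p_min))
  }

  if ("harmonize" %in% stages) {
    target <- need("target", "qc")
    ss_raw <- tryCatch(read_sumstats(config$paths$sumstats),
                       error = function(e)
                         stop("harmonize failed on ",
                              config$paths$sumstats, ": ",
                              conditionMessage(e)))
    h <- harmonize_alleles(ss_raw, target$variants)
    assign("ss", h$sumstats, envir = state)
    manifest <- write_stage_table(h$report, out_dir, "harmonization_report",
                                  manifest, "harmonize", "defaults")
    manifest <- write_stage_table(h$sumstats, out_dir, "harmonized_sumstats",
                                  manifest, "harmonize", "defaults")
    if (!is.null(config$paths$sumstats_longevity)) {
      hl <- harmonize_alleles(read_sumstats(config$paths$sumstats_longevity),
                              target$variants)
      assign("ss_longevity", hl$sumstats, envir = state)
    }
  }

  if ("scan" %in% stages) {
    target <- need("target", "qc")
    ss <- need("ss", "harmonize")
    clump <- greedy_clump(ss, target$genotypes, p$r2_threshold, window_bp)
    scan <- threshold_scan(ss, target$genotypes, get("pheno", state), clump)
    assign("scan", scan, envir = state)
    manifest <- write_stage_table(scan$table, out_dir, "threshold_scan",
                                  manifest, "scan",
                                  sprintf("r2=%g,window_kb=%g",
                                          p$r2_threshold, p$window_kb))
    utils::write.table(
      data.frame(id = names(scan$best_scores), score = scan$best_scores),
      file.path(out_dir, "best_prs_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("bins" %in% stages) {
    target <- need("target", "qc")
    ss <- need("ss", "harmonize")
    bins <- pvalue_bin_prs_scan(ss, target$genotypes, get("pheno", state),
                                r2_threshold = p$r2_threshold,
                                window_bp = window_bp, alpha = p$alpha)
    assign("bins", bins, envir = state)
    manifest <- write_stage_table(bins, out_dir, "pvalue_bin_scan",
                                  manifest, "bins", "default cutpoints")
  }

  if ("stratify" %in% stages) {
    target <- need("target", "qc")
    ss <- need("ss", "harmonize")
    sets <- if (exists("sets", envir = state)) get("sets", envir = state)
            else if (!is.null(config$paths$annotations_bed)) {
              groups <- if (!is.null(config$paths$set_groups))
                read_set_groups(config$paths$set_groups)
              snps_in_sets(target$variants,
                           bed = read_bed_sets(config$paths$annotations_bed),
                           groups = groups)
            }
    if (is.null(sets)) {
      message("no annotation sets configured; stratify stage skipped")
    } else {
      strat <- set_prs_scan(ss, target$genotypes, get("pheno", state), sets,
                            r2_threshold = p$r2_threshold,
                            window_bp = window_bp, alpha = p$alpha)
      assign("strat", strat, envir = state)
      manifest <- write_stage_table(strat, out_dir, "set_scan", manifest,
                                    "stratify", "threshold=1")
    }
  }

  if ("mask" %in% stages) {
    target <- need("target", "qc")
    ss <- need("ss", "harmonize")
    region <- config$mask_region
    if (is.null(region)) {
      message("no mask_region configured; mask stage skipped")
    } else {
      ss_m <- mask_region(ss, region)
      clump_m <- greedy_clump(ss_m, target$genotypes, p$r2_threshold,
                              window_bp)
      scan_m <- threshold_scan(ss_m, target$genotypes, get("pheno", state),
                               clump_m)
      manifest <- write_stage_table(scan_m$table, out_dir,
                                    "masked_threshold_scan", manifest,
                                    "mask", sprintf("%s:%d-%d", region$chrom,
                                                    region$start, region$end))
    }
  }

  if ("dissect" %in% stages) {
    scan <- need("scan", "scan")
    if (!exists("ss_longevity", envir = state)) {
      message("no longevity sumstats configured; dissect stage skipped")
    } else {
      ss_risk <- orient_to_risk(need("ss", "harmonize"))
      panel <- select_pleiotropic(scan$best_snps, ss_risk,
                                  get("ss_longevity", state),
                                  alpha = p$alpha)
      if (!is.null(config$paths$genes)) {
        genes <- read_genes(config$paths$genes)
        target <- need("target", "qc")
        pos <- target$variants[match(panel$snp_id, target$variants$snp_id),
                               c("snp_id", "chrom", "pos")]
        panel$gene_label <- unname(annotate_nearest_genes(pos, genes))
      }
      assign("panel", panel, envir = state)
      manifest <- write_stage_table(panel, out_dir, "pleiotropy_panels",
                                    manifest, "dissect",
                                    sprintf("alpha=%g", p$alpha))
    }
  }

  if ("predict" %in% stages) {
    features <- list()
    if (exists("bins", envir = state)) {
      sc <- attr(get("bins", state), "scores")
      names(sc) <- paste0("bin_", get("bins", state)$label)
      features <- c(features, sc)
    }
    if (exists("strat", envir = state)) {
      sc <- attr(get("strat", state), "scores")
      names(sc) <- paste0("set_", get("strat", state)$label)
      features <- c(features, sc)
    }
    if (exists("scan", envir = state))
      features$best_prs <- get("scan", state)$best_scores
    if (length(features) < 2) {
      message("fewer than 2 PRS features available; predict stage skipped")
    } else {
      xm <- assemble_prs_matrix(features)
      yv <- get("pheno", state)[rownames(xm)]
      report <- model_selection_cv(
        xm, yv, families = default_model_grid()[p$cv_families],
        k = p$cv_k, iterations = p$cv_iterations, seed = config$seed)
      assign("prediction", report, envir = state)
      manifest <- write_stage_table(report$cv_table, out_dir,
                                    "prediction_cv", manifest, "predict",
                                    sprintf("k=%d,iters=%d", p$cv_k,
                                            p$cv_iterations))
      utils::write.table(
        data.frame(trait = names(report$coefficients),
                   coefficient = report$coefficients),
        file.path(out_dir, "prediction_coefficients.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest_tbl <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stage = character(0), output = character(0),
               md5 = character(0), n_rows = integer(0),
               params = character(0))
  utils::write.table(manifest_tbl, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(as.list(state), list(manifest = manifest_tbl)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
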