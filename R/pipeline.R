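# End-to-end orchestration: simulate -> filter -> PCA/outliers -> global
# ancestry -> local ancestry -> karyotype prediction -> introgression scan,
# from one config, with a fixed seed and a machine-readable manifest.

#' Default pipeline configuration
#'
#' Analysis parameters default to the published workflow values: MAF > 0.05
#' and missingness < 0.05, HMM with g = 25 generations, r = 1e-8 and
#' ancestry priors 0.30/0.66/0.04 (WB/EUR_DP/ASIA_DP), 200 bootstrap
#' replicates, flank window 1, scan thresholds at 3 and 6 SD, chr17 length
#' 63,494,081 bp. Simulation sizes are the package's demo scale.
#'
#' @return nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "results/pipeline",
    sim = list(
      n_snps = 3000L,
      panel_sizes = list(WB = 60L, EUR_DP = 60L, ASIA_DP = 40L),
      divergence = list(WB = 0.15, EUR_DP = 0.15, ASIA_DP = 0.30),
      missing_rate = 0.02,
      cohort = list(n_pure = 60L, n_f1 = 20L, n_f2 = 30L, n_bc = 40L,
                    bc_depths = c(2L, 3L))),
    filters = list(maf_min = 0.05, miss_max = 0.05),
    ibs_threshold = 0.95,
    hmm = list(g = 25, r = 1e-8,
               priors = list(WB = 0.30, EUR_DP = 0.66, ASIA_DP = 0.04)),
    n_boot = 200L,
    flank_window = 1L,
    k_sd = c(3, 6),
    max_gap = 0L,
    chr17_length = 63494081
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        length(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      # explicit empties/NULLs override the default rather than merging,
      # so a deliberately missing section is caught by validation
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param x path to a YAML file, or a (partial) configuration list;
#'   unspecified fields take [default_config()] values.
#' @return validated configuration list.
#' @export
load_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  cfg <- merge_config(default_config(), x)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  req <- c("seed", "out_dir", "sim", "filters", "hmm", "n_boot",
           "flank_window", "k_sd", "chr17_length")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("config validation failed; missing field(s): ",
         paste(missing, collapse = ", "))
  if (is.null(cfg$sim$panel_sizes) || !length(cfg$sim$panel_sizes))
    stop("config validation failed: sim$panel_sizes (reference panel spec) ",
         "is required")
  if (is.null(cfg$sim$n_snps) || cfg$sim$n_snps < 10)
    stop("config validation failed: sim$n_snps must be at least 10")
  stopifnot(cfg$seed == as.integer(cfg$seed))
  invisible(cfg)
}

write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulates reference panels and an admixed cohort (mixed pure wild,
#' F1, F2 and backcross pedigrees), writes the genotypes and truth, then
#' filters SNPs, thins duplicate samples, runs PCA with mixture-model
#' outlier flagging, supervised global ancestry with bootstrap CIs, the
#' local-ancestry HMM, junction karyotype prediction with concordance
#' against truth, and the low-ancestry genome scan. All stage outputs are
#' plain text under `out_dir`; re-running with the same config and seed
#' reproduces them byte for byte.
#'
#' @param config a configuration list or YAML path (see [load_config()]).
#' @return the run manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  manifest <- list(seed = seed, parameters = cfg[setdiff(names(cfg), "out_dir")],
                   stages = list())
  note <- function(stage_name, ...) {
    manifest$stages[[stage_name]] <<- list(...)
  }

  # -- simulate ---------------------------------------------------------
  panels <- stage("simulate", {
    model <- population_model(
      n_snps = cfg$sim$n_snps,
      divergence = unlist(cfg$sim$divergence),
      missing_rate = cfg$sim$missing_rate)
    generate_reference_panels(model, unlist(cfg$sim$panel_sizes), seed = seed)
  })
  cohort <- stage("simulate", sim_demo_cohort(panels, cfg$sim$cohort,
                                              seed = seed + 1L))
  gm <- cohort_genotypes(cohort, panels$map)
  truth <- truth_table(cohort)
  write_plink(gm, file.path(cfg$out_dir, "cohort"))
  write_truth_tracts(cohort, file.path(cfg$out_dir, "truth_tracts.tsv"))
  write_truth_karyotypes(cohort, file.path(cfg$out_dir, "truth_karyotypes.tsv"))
  write_tsv(data.frame(snp = panels$map$id, chrom = panels$map$chrom,
                       pos = panels$map$pos, panels$panel$freq),
            file.path(cfg$out_dir, "panel_freqs.tsv"), seed)
  note("simulate", n_snps = nrow(panels$map), n_cohort = length(cohort),
       panel_sizes = lapply(panels$genotypes, function(g) nrow(g$geno)))

  # -- filter -----------------------------------------------------------
  gm_f <- stage("filter", filter_snps(gm, cfg$filters$maf_min,
                                      cfg$filters$miss_max))
  keep_snps <- match(gm_f$map$id, panels$map$id)
  panel_f <- ref_panel(panels$panel$freq[keep_snps, , drop = FALSE], gm_f$map)
  kept_ids <- stage("filter", ibs_thin(gm_f, cfg$ibs_threshold))
  gm_f <- subset_inds(gm_f, match(kept_ids, gm_f$ids))
  note("filter", snps_kept = nrow(gm_f$map), snps_input = nrow(gm$map),
       individuals_kept = length(kept_ids))

  # -- pca + outliers ---------------------------------------------------
  scores <- stage("pca", pca_genotypes(gm_f, n_components = 10L))
  outliers <- stage("pca", detect_outliers(scores))
  write_tsv(data.frame(id = scores$ids, scores$scores),
            file.path(cfg$out_dir, "pca_scores.tsv"), seed)
  write_tsv(outliers, file.path(cfg$out_dir, "outlier_calls.tsv"), seed)
  note("pca", explained_pc1 = scores$explained[1],
       explained_pc2 = scores$explained[2],
       n_outliers = sum(outliers$is_outlier))

  # -- global ancestry --------------------------------------------------
  qtab <- stage("ancestry_q",
                ancestry_q_table(gm_f, panel_f, n_boot = cfg$n_boot,
                                 seed = seed + 2L))
  write_tsv(qtab, file.path(cfg$out_dir, "q_matrix.tsv"), seed)
  note("ancestry_q", n_boot = cfg$n_boot,
       n_unadmixed = sum(qtab$class == "unadmixed"),
       n_admixed = sum(qtab$class == "admixed"),
       n_recent_hybrid = sum(qtab$class == "recent_hybrid_candidate"))

  # -- local ancestry ---------------------------------------------------
  hmm <- stage("lai", build_hmm(panel_f, priors = unlist(cfg$hmm$priors),
                                g = cfg$hmm$g, r = cfg$hmm$r))
  field <- stage("lai", posterior_dosages(hmm, gm_f))
  write_dosages(field, cfg$out_dir)
  note("lai", n_individuals = length(field$ids),
       mean_loglik = mean(field$loglik))

  # -- karyotype --------------------------------------------------------
  kary <- stage("karyotype", {
    m15 <- gm_f$map[gm_f$map$chrom == "15", , drop = FALSE]
    m17 <- gm_f$map[gm_f$map$chrom == "17", , drop = FALSE]
    class(m15) <- class(m17) <- c("snp_map", "data.frame")
    fmap <- fuse_map(m15, m17, cfg$chr17_length)
    calls <- predict_karyotype(field, fmap, cfg$flank_window)
    truth_f <- truth[truth$id %in% calls$id, ]
    conc <- karyotype_concordance(calls, truth_f)
    tfield <- truth_dosages(cohort[match(calls$id,
                                         vapply(cohort, `[[`, "", "id"))],
                            gm_f$map)
    calls_truth <- predict_karyotype(tfield, fmap, cfg$flank_window)
    conc_truth <- karyotype_concordance(calls_truth, truth_f)
    write_fused_map(fmap, file.path(cfg$out_dir, "fused_map.tsv"))
    write_tsv(calls, file.path(cfg$out_dir, "karyotype_calls.tsv"), seed)
    write_tsv(as.data.frame.matrix(conc$confusion),
              file.path(cfg$out_dir, "karyotype_confusion.tsv"), seed)
    list(conc = conc, conc_truth = conc_truth)
  })
  note("karyotype", overall_concordance = kary$conc$overall,
       concordance_on_truth_dosages = kary$conc_truth$overall)

  # -- scan -------------------------------------------------------------
  scan <- stage("scan", ancestry_scan(field))
  write_tsv(as.data.frame(scan), file.path(cfg$out_dir, "scan.tsv"), seed)
  flag_counts <- list()
  for (k in cfg$k_sd) {
    regs <- stage("scan", flag_regions(scan, k_sd = k,
                                       max_gap = cfg$max_gap))
    write_regions(regs,
                  bed_path = file.path(cfg$out_dir,
                                       sprintf("flagged_%gsd.bed", k)),
                  tsv_path = file.path(cfg$out_dir,
                                       sprintf("flagged_%gsd.tsv", k)))
    flag_counts[[sprintf("k%g", k)]] <- nrow(regs)
  }
  note("scan", mu = attr(scan, "mu"), sigma = attr(scan, "sigma"),
       flagged = flag_counts)

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate the demo cohort used by the pipeline
#'
#' A mixture of pure wild boar (2n = 36), F1 (37), F2 (36/37/38) and
#' wild-backcross pedigrees, each with known tract and karyotype truth.
#'
#' @param panels a `sim_panels` object.
#' @param spec list with `n_pure`, `n_f1`, `n_f2`, `n_bc`, `bc_depths`.
#' @param seed integer seed.
#' @return list of `sim_individual` with genotypes emitted.
#' @export
sim_demo_cohort <- function(panels, spec, seed = 1L) {
  set.seed(seed)
  cl <- panels$model$chrom_lengths
  lb <- panels$model$labels
  wb <- lb[1]; dp <- lb[2]
  mr <- panels$model$missing_rate
  fo <- function(pop) founder_individual(pop, cl, labels = lb)
  out <- list()
  for (i in seq_len(spec$n_pure)) {
    ind <- cross_once(fo(wb), fo(wb), sprintf("pure_%03d", i), 1e-8)
    out[[length(out) + 1L]] <- emit_genotypes(ind, panels$panel, mr)
  }
  for (i in seq_len(spec$n_f1)) {
    ind <- cross_once(fo(wb), fo(dp), sprintf("f1_%03d", i), 1e-8)
    out[[length(out) + 1L]] <- emit_genotypes(ind, panels$panel, mr)
  }
  for (i in seq_len(spec$n_f2)) {
    pA <- cross_once(fo(wb), fo(dp), "tmpA", 1e-8)
    pB <- cross_once(fo(wb), fo(dp), "tmpB", 1e-8)
    ind <- cross_once(pA, pB, sprintf("f2_%03d", i), 1e-8)
    out[[length(out) + 1L]] <- emit_genotypes(ind, panels$panel, mr)
  }
  bc <- backcross_cohort(panels, spec$n_bc,
                         depths = rep_len(unlist(spec$bc_depths), spec$n_bc),
                         emit = TRUE, missing_rate = mr)
  for (i in seq_along(bc)) bc[[i]]$id <- sprintf("bc_%03d", i)
  c(out, bc)
}
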