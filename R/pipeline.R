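# End-to-end pipeline: simulate -> genotype QC -> phenotype prep -> fusion
# -> stability -> association -> gene tests -> enrichment, with every
# stage's outputs, the echoed configuration, and a run manifest written
# under one run directory.

#' Pipeline configuration
#'
#' Collects every tunable of the chain in one place; the serialised copy is
#' embedded in each run directory so runs are self-describing.
#'
#' @param out_dir Run directory.
#' @param seed Master seed; stage seeds derive from it.
#' @param synthetic [synthetic_config()] for the simulate stage, or `NULL`
#'   to read `genotypes_path` / `volumes_dir` / `covariates_path` instead.
#' @param genotypes_path,volumes_dir,covariates_path External inputs
#'   (PLINK prefix or dosage TSV; NIfTI directory; TSV).
#' @param gene_bed,pathways_gmt Optional gene intervals (BED) and pathway
#'   sets (GMT); synthesised from the simulated map when `NULL`.
#' @param min_call_rate,min_maf,hwe_alpha Variant QC thresholds.
#' @param ld_window,ld_step,ld_r2_max LD pruning controls (window 50,
#'   step 5, r2 0.7).
#' @param n_pca_axes,n_ancestry_axes Stratification PCA controls.
#' @param prefilter_alpha Logistic screening threshold (p < 0.1).
#' @param fwhm_mm,voxel_size_mm Smoothing kernel and voxel geometry.
#' @param K_gene,K_brain Component-count overrides; `NULL` uses MDL.
#' @param lambda,tau_link,r_cap,n_couple,max_epochs,batch_size,tol Fusion
#'   controls (see [run_para_ica()]).
#' @param z_thresh,min_cluster,connectivity Component-map thresholding
#'   (|z| > 1.5, k > 50).
#' @param run_stability,stability_repeats,holdout_frac,tau_stab Stability
#'   stage controls (5% holdout).
#' @param assoc_alpha Pair-test family-wise alpha (0.05).
#' @param gene_alpha Dominant-gene threshold (p < 0.05).
#' @param gene_test_sims Monte-Carlo draws per gene.
#' @param enrich_alpha Reporting threshold on enrichment q.
#' @param write_nifti Write NIfTI volumes/maps (disable for quick runs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("parafuse_run_"),
                            seed = 1,
                            synthetic = synthetic_config(seed = seed),
                            genotypes_path = NULL, volumes_dir = NULL,
                            covariates_path = NULL,
                            gene_bed = NULL, pathways_gmt = NULL,
                            min_call_rate = 0.95, min_maf = 0.01,
                            hwe_alpha = 1e-6,
                            ld_window = 50, ld_step = 5, ld_r2_max = 0.7,
                            n_pca_axes = 10, n_ancestry_axes = 2,
                            prefilter_alpha = 0.1,
                            fwhm_mm = 4, voxel_size_mm = c(1, 1, 1),
                            K_gene = NULL, K_brain = NULL,
                            lambda = 1, tau_link = 0.25, r_cap = 0.95,
                            n_couple = 1, max_epochs = 400,
                            batch_size = 128, tol = 1e-5,
                            z_thresh = 1.5, min_cluster = 50,
                            connectivity = 26,
                            run_stability = FALSE, stability_repeats = 10,
                            holdout_frac = 0.05, tau_stab = 0.8,
                            assoc_alpha = 0.05, gene_alpha = 0.05,
                            gene_test_sims = 10000, enrich_alpha = 0.05,
                            write_nifti = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing each stage's outputs
#' under `out_dir` together with a JSON echo of the configuration and a run
#' manifest (stage timings, seeds, output checksums).  Rerunning with the
#' same configuration reproduces all outputs bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list: the manifest plus in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- config
  cfg_json$synthetic <- unclass(config$synthetic)
  jsonlite::write_json(
    lapply(unclass(cfg_json), function(x) if (is.function(x)) NULL else x),
    file.path(out, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  timings <- list()
  stage_dir <- function(nm) {
    d <- file.path(out, nm)
    dir.create(d, showWarnings = FALSE)
    d
  }
  results <- list()

  # -- simulate / load ------------------------------------------------------
  tic <- Sys.time()
  d <- stage_dir("01_input")
  if (!is.null(config$synthetic)) {
    ds <- generate_linked_dataset(config$synthetic)
    geno <- ds$genotypes
    covars <- ds$covariates
    volumes <- lapply(seq_len(dim(ds$volumes)[4]),
                      function(s) ds$volumes[, , , s])
    mask <- ds$mask
    write_plink(geno, file.path(d, "genotypes"))
    write_tsv(covars, file.path(d, "covariates.tsv"))
    write_truth_bundle(ds$truth, file.path(d, "truth"))
    if (config$write_nifti) {
      write_nifti_volumes(ds$volumes, mask, file.path(d, "volumes"),
                          config$voxel_size_mm, ids = covars$id)
    }
    results$synthetic <- ds
  } else {
    geno <- read_genotypes(config$genotypes_path)
    nif <- read_nifti_volumes(config$volumes_dir)
    covars <- read_tsv(config$covariates_path)
    if (!setequal(nif$ids, covars$id)) {
      stop_pf("volume ids do not match covariate ids")
    }
    volumes <- nif$volumes[match(covars$id, nif$ids)]
    mask <- nif$mask
  }
  timings$input <- as.numeric(Sys.time() - tic, units = "secs")

  # -- genotype QC ----------------------------------------------------------
  tic <- Sys.time()
  d <- stage_dir("02_qc")
  fv <- filter_variants(geno, config$min_call_rate, config$min_maf,
                        config$hwe_alpha)
  qc_report_write(fv$report, d)
  pruned_ids <- ld_prune(fv$genotypes, config$ld_window, config$ld_step,
                         config$ld_r2_max)
  keep <- fv$genotypes$snp_records$id %in% pruned_ids
  G2 <- genotype_matrix(fv$genotypes$dosages[, keep, drop = FALSE],
                        fv$genotypes$snp_records[keep, , drop = FALSE],
                        fv$genotypes$sample_records)
  writeLines(pruned_ids, file.path(d, "ld_pruned_ids.txt"))

  pca <- eigenstrat_pca(G2, config$n_pca_axes)
  eth <- covars$subpop %||% covars$ethnicity %||% rep(1, nrow(covars))
  axes <- select_ancestry_axes(pca$eigenvectors, eth,
                               config$n_ancestry_axes)
  EV <- pca$eigenvectors[, axes, drop = FALSE]
  colnames(EV) <- paste0("EV", seq_len(ncol(EV)))
  write_tsv(cbind(id = covars$id, as.data.frame(pca$eigenvectors)),
            file.path(d, "eigenvectors.tsv"))

  D_complete <- G2$dosages
  for (j in seq_len(ncol(D_complete))) {      # mean imputation pre-fusion
    mis <- is.na(D_complete[, j])
    if (any(mis)) D_complete[mis, j] <- mean(D_complete[, j], na.rm = TRUE)
  }
  D_resid <- regress_out_covariates(D_complete, EV)
  pre_covars <- cbind(age = covars$age, sex = covars$sex, EV)
  pf <- logistic_prefilter(D_resid, covars$group, pre_covars,
                           config$prefilter_alpha)
  write_tsv(data.frame(snp = names(pf$p), p = pf$p,
                       retained = names(pf$p) %in% pf$retained,
                       flagged = names(pf$p) %in% pf$flagged),
            file.path(d, "prefilter.tsv"))
  sel <- colnames(D_resid) %in% pf$retained
  X_gene <- D_resid[, sel, drop = FALSE]
  snp_records_fused <- G2$snp_records[sel, , drop = FALSE]
  results$qc <- list(report = fv$report, pruned = pruned_ids,
                     eigenvectors = pca$eigenvectors, axes = axes,
                     prefilter = pf, n_fused = ncol(X_gene))
  timings$qc <- as.numeric(Sys.time() - tic, units = "secs")

  # -- phenotype prep -------------------------------------------------------
  tic <- Sys.time()
  d <- stage_dir("03_prep")
  smoothed <- lapply(volumes, gaussian_smooth, fwhm_mm = config$fwhm_mm,
                     voxel_size_mm = config$voxel_size_mm)
  pheno <- mask_and_flatten(smoothed, mask, config$voxel_size_mm)
  X_brain <- pheno$values
  writeLines(jsonlite::toJSON(list(n_voxels = ncol(X_brain),
                                   ordering = pheno$ordering),
                              auto_unbox = TRUE),
             file.path(d, "phenotype_meta.json"))
  timings$prep <- as.numeric(Sys.time() - tic, units = "secs")

  # -- fusion ---------------------------------------------------------------
  tic <- Sys.time()
  d <- stage_dir("04_fusion")
  K_gene <- config$K_gene %||% estimate_order_mdl(X_gene)$K
  K_brain <- config$K_brain %||% estimate_order_mdl(X_brain)$K
  K_gene <- max(1L, min(K_gene, nrow(X_gene) - 1L))
  K_brain <- max(1L, min(K_brain, nrow(X_brain) - 1L))
  fus_seed <- derive_seeds(config$seed, 3)
  fusion <- run_para_ica(X_gene, X_brain, K_gene, K_brain,
                         lambda = config$lambda, tau_link = config$tau_link,
                         r_cap = config$r_cap, n_couple = config$n_couple,
                         max_epochs = config$max_epochs,
                         batch_size = config$batch_size, tol = config$tol,
                         seed = fus_seed[1])
  write_tsv(cbind(id = covars$id, as.data.frame(fusion$gene_model$loadings)),
            file.path(d, "gene_loadings.tsv"))
  write_tsv(cbind(id = covars$id, as.data.frame(fusion$brain_model$loadings)),
            file.path(d, "brain_loadings.tsv"))
  write_tsv(fusion$linked_pairs, file.path(d, "linked_pairs.tsv"))
  jsonlite::write_json(fusion$objective_trace, file.path(d, "trace.json"),
                       dataframe = "columns", digits = NA, na = "null")
  clusters <- lapply(seq_len(K_brain), function(k) {
    ct <- threshold_component_map(fusion$brain_model$sources[k, ], mask,
                                  config$z_thresh, config$min_cluster,
                                  config$connectivity)
    if (nrow(ct) > 0) cbind(component = k, ct[, 1:5]) else NULL
  })
  cl_tab <- do.call(rbind, clusters[!vapply(clusters, is.null, TRUE)])
  if (!is.null(cl_tab)) write_tsv(cl_tab, file.path(d, "clusters.tsv"))
  if (config$write_nifti) {
    for (k in seq_len(K_brain)) {
      write_component_map(fusion$brain_model$sources[k, ], mask,
                          file.path(d, sprintf("brain_ic%02d_z.nii.gz", k)),
                          config$voxel_size_mm)
    }
  }
  results$fusion <- fusion
  results$K <- c(gene = K_gene, brain = K_brain)
  results$clusters <- cl_tab
  timings$fusion <- as.numeric(Sys.time() - tic, units = "secs")

  # -- stability ------------------------------------------------------------
  if (config$run_stability) {
    tic <- Sys.time()
    d <- stage_dir("05_stability")
    stab <- loo_stability(
      X_gene, X_brain,
      fusion_config = list(K_gene = K_gene, K_brain = K_brain,
                           lambda = config$lambda,
                           tau_link = config$tau_link, r_cap = config$r_cap,
                           max_epochs = config$max_epochs,
                           batch_size = config$batch_size,
                           tol = config$tol, seed = fus_seed[2]),
      holdout_frac = config$holdout_frac,
      repeats = config$stability_repeats,
      tau_stab = config$tau_stab, seed = fus_seed[2])
    write_tsv(stab$gene, file.path(d, "gene_stability.tsv"))
    write_tsv(stab$brain, file.path(d, "brain_stability.tsv"))
    jsonlite::write_json(list(percent_stable = as.list(stab$percent_stable),
                              mean_correlation = as.list(stab$mean_correlation),
                              repeats = stab$repeats,
                              tau_stab = stab$tau_stab),
                         file.path(d, "stability.json"),
                         auto_unbox = TRUE, digits = NA)
    results$stability <- stab
    timings$stability <- as.numeric(Sys.time() - tic, units = "secs")
  }

  # -- association ----------------------------------------------------------
  tic <- Sys.time()
  d <- stage_dir("06_association")
  Z <- cbind(age = covars$age, sex = covars$sex, EV, group = covars$group)
  pairs <- test_all_pairs(fusion$gene_model$loadings,
                          fusion$brain_model$loadings, Z,
                          config$assoc_alpha)
  write_tsv(pairs, file.path(d, "pair_tests.tsv"))
  gd_gene <- group_difference_tests(fusion$gene_model$loadings, covars$group)
  gd_brain <- group_difference_tests(fusion$brain_model$loadings,
                                     covars$group)
  write_tsv(gd_gene, file.path(d, "group_diff_gene.tsv"))
  write_tsv(gd_brain, file.path(d, "group_diff_brain.tsv"))
  clin_cols <- grep("_score$", names(covars), value = TRUE)
  clin <- NULL
  if (length(clin_cols) > 0) {
    clin <- clinical_correlations(fusion$brain_model$loadings,
                                  covars[clin_cols],
                                  cbind(age = covars$age, sex = covars$sex))
    write_tsv(clin, file.path(d, "clinical_correlations.tsv"))
  }
  results$association <- list(pairs = pairs, group_gene = gd_gene,
                              group_brain = gd_brain, clinical = clin)
  timings$association <- as.numeric(Sys.time() - tic, units = "secs")

  # -- gene-based tests + enrichment ---------------------------------------
  tic <- Sys.time()
  d <- stage_dir("07_genes")
  gene_model <- if (!is.null(config$gene_bed)) read_gene_bed(config$gene_bed)
    else synth_gene_model(snp_records_fused, seed = derive_seeds(config$seed, 4)[4])
  ann <- annotate_snps_to_genes(snp_records_fused, gene_model)
  # component of interest: gene side of the strongest significant pair,
  # else the strongest linked pair, else component 1
  sig <- pairs[!is.na(pairs$significant) & pairs$significant, ]
  comp <- if (nrow(sig) > 0) sig$gene[which.min(sig$p)]
          else if (nrow(fusion$linked_pairs) > 0) fusion$linked_pairs$gene[1]
          else 1L
  snp_p <- component_snp_pvalues(fusion$gene_model$sources[comp, ])
  names(snp_p) <- snp_records_fused$id
  gene_seeds <- derive_seeds(fus_seed[3], max(1L, length(unique(ann$assignments$gene))))
  genes <- sort(unique(ann$assignments$gene))
  gene_tab <- do.call(rbind, lapply(seq_along(genes), function(gi) {
    snps <- ann$assignments$snp[ann$assignments$gene == genes[gi]]
    jj <- match(snps, snp_records_fused$id)
    Sigma <- suppressWarnings(
      cor(X_gene[, jj, drop = FALSE], use = "pairwise.complete.obs"))
    Sigma[is.na(Sigma)] <- 0
    diag(Sigma) <- 1
    gt <- gene_based_test(snp_p[jj], Sigma, n_sims = config$gene_test_sims,
                          seed = gene_seeds[gi])
    data.frame(gene = genes[gi], n_snps = length(jj), T = gt$T, p = gt$p,
               se = gt$se, n_sims = gt$n_sims)
  }))
  write_tsv(gene_tab, file.path(d, "gene_tests.tsv"))
  gene_p <- setNames(gene_tab$p, gene_tab$gene)
  selected <- select_component_genes(gene_p, config$gene_alpha)
  writeLines(selected, file.path(d, "selected_genes.txt"))
  results$genes <- list(component = comp, table = gene_tab,
                        selected = selected, annotation = ann)
  timings$genes <- as.numeric(Sys.time() - tic, units = "secs")

  tic <- Sys.time()
  d <- stage_dir("08_enrichment")
  background <- sort(unique(ann$assignments$gene))
  pathways <- if (!is.null(config$pathways_gmt)) read_gmt(config$pathways_gmt)
    else synth_pathways(background, enriched_genes = head(selected, 5),
                        seed = derive_seeds(config$seed, 5)[5])
  enr <- if (length(selected) > 0) {
    hypergeometric_enrichment(selected, pathways, background)
  } else {
    hypergeometric_enrichment(character(0), pathways, background)
  }
  write_tsv(enr, file.path(d, "enrichment.tsv"))
  results$enrichment <- enr
  timings$enrichment <- as.numeric(Sys.time() - tic, units = "secs")

  # -- manifest -------------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("parafuse")),
    seed = config$seed,
    derived_fusion_seeds = fus_seed,
    timings_sec = timings,
    total_sec = as.numeric(Sys.time() - t0, units = "secs"),
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              sub(paste0(out, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

qc_report_write <- function(report, dir) {
  write_tsv(data.frame(filter = names(report$removed),
                       removed = as.integer(report$removed)),
            file.path(dir, "qc_report.tsv"))
  jsonlite::write_json(
    list(n_input = report$n_input, removed = as.list(report$removed),
         thresholds = as.list(report$thresholds),
         retained = report$retained_ids),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}
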