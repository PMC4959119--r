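#!/usr/bin/env Rscript
# Stage 2 -- genotype quality control and SNP selection.
#
# Reads the PLINK fileset, applies variant QC (call rate, MAF, exact HWE in
# controls), prunes LD at the published window-50 / step-5 / r2 0.7
# settings, computes EIGENSTRAT-style ancestry axes, selects the axes
# associated with self-reported ancestry, regresses them out, and screens
# SNPs by logistic regression on diagnosis (uncorrected p < 0.1).  The
# residualised dosages of retained SNPs are what the fusion stage consumes.

suppressPackageStartupMessages(library(parafuse))

inp <- "results/study/01_input"
out <- "results/study/02_qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geno <- read_genotypes(file.path(inp, "genotypes"))
covars <- read_tsv(file.path(inp, "covariates.tsv"))

fv <- filter_variants(geno, min_call_rate = 0.95, min_maf = 0.01,
                      hwe_alpha = 1e-6)
cat(sprintf("variant QC: %d in, removed %s, %d retained\n",
            fv$report$n_input,
            paste(names(fv$report$removed), fv$report$removed,
                  sep = "=", collapse = ", "),
            length(fv$report$retained_ids)))

pruned <- ld_prune(fv$genotypes, window_snps = 50, step_snps = 5,
                   r2_max = 0.7)
cat(sprintf("LD pruning (window 50, step 5, r2 0.7): %d -> %d SNPs\n",
            length(fv$report$retained_ids), length(pruned)))
keep <- fv$genotypes$snp_records$id %in% pruned
G <- genotype_matrix(fv$genotypes$dosages[, keep, drop = FALSE],
                     fv$genotypes$snp_records[keep, , drop = FALSE],
                     fv$genotypes$sample_records)

pca <- eigenstrat_pca(G, 10)
axes <- select_ancestry_axes(pca$eigenvectors, covars$subpop, 2)
cat(sprintf("ancestry axes selected by ANOVA vs self-reported ancestry: %s\n",
            paste(axes, collapse = ", ")))
EV <- pca$eigenvectors[, axes, drop = FALSE]
colnames(EV) <- paste0("EV", seq_along(axes))

D <- G$dosages
for (j in seq_len(ncol(D))) {
  mis <- is.na(D[, j])
  if (any(mis)) D[mis, j] <- mean(D[, j], na.rm = TRUE)
}
D_resid <- regress_out_covariates(D, EV)

pf <- logistic_prefilter(D_resid, covars$group,
                         cbind(age = covars$age, sex = covars$sex, EV),
                         alpha = 0.1)
cat(sprintf("logistic pre-filter (p < 0.1): %d of %d SNPs retained (%d flagged)\n",
            length(pf$retained), ncol(D_resid), length(pf$flagged)))

sel <- colnames(D_resid) %in% pf$retained
X_gene <- D_resid[, sel, drop = FALSE]
write_tsv(cbind(id = covars$id, as.data.frame(X_gene)),
          file.path(out, "fusion_dosages.tsv"))
write_tsv(G$snp_records[sel, ], file.path(out, "fusion_snps.tsv"))
write_tsv(cbind(id = covars$id, as.data.frame(EV)),
          file.path(out, "ancestry_axes.tsv"))
write_tsv(data.frame(snp = names(pf$p), p = pf$p),
          file.path(out, "prefilter_p.tsv"))
cat(sprintf("fusion input: %d subjects x %d SNPs\n", nrow(X_gene),
            ncol(X_gene)))
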