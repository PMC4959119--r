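#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# Generates the linked genotype + gray-matter dataset at the study scale:
# 198 adolescents (63 patients), two ancestral subpopulations at FST 0.1,
# 2000 exome-chip-like SNPs in LD blocks, a 12x12x12 voxel grid with
# K = 4 genetic / 3 brain latent components, and one cross-modality linked
# pair at r = 0.34 whose loadings are shifted by 0.5 SD in the patient
# group.  Writes PLINK binary genotypes, per-subject NIfTI volumes, the
# covariate table, and the ground-truth bundle.

suppressPackageStartupMessages(library(parafuse))

out <- "results/study/01_input"
unlink(out, recursive = TRUE)        # stale volumes would scramble ids
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 20260924)
ds <- generate_linked_dataset(cfg)

write_plink(ds$genotypes, file.path(out, "genotypes"))
write_tsv(ds$covariates, file.path(out, "covariates.tsv"))
write_truth_bundle(ds$truth, file.path(out, "truth"))
write_nifti_volumes(ds$volumes, ds$mask, file.path(out, "volumes"),
                    ids = ds$covariates$id)

gm <- synth_gene_model(ds$genotypes$snp_records, seed = 20260924)
write_gene_bed(gm, file.path(out, "genes.bed"))
# the first pathway is seeded with the genes harbouring the linked genetic
# component's SNPs, giving the enrichment stage a known positive
ann <- annotate_snps_to_genes(ds$genotypes$snp_records, gm)
causal_snps <- ds$genotypes$snp_records$id[ds$truth$gene_sources[1, ] != 0]
causal_genes <- unique(ann$assignments$gene[ann$assignments$snp %in%
                                              causal_snps])
pw <- synth_pathways(gm$symbol, n_pathways = 30,
                     enriched_genes = causal_genes, seed = 20260924)
write_gmt(pw, file.path(out, "pathways.gmt"))

maf <- apply(ds$gene, 2, function(x) min(mean(x) / 2, 1 - mean(x) / 2))
cat(sprintf("cohort: %d subjects (%d patients), %d SNPs, %s grid\n",
            cfg$n_subjects, sum(ds$covariates$group), cfg$n_snps,
            paste(cfg$grid_dims, collapse = "x")))
cat(sprintf("realized link correlation (target %.2f): %.3f\n",
            cfg$linked_pairs[[1]][3], ds$truth$realized_link_correlations))
cat(sprintf("realized Hudson FST (target %.2f): %.3f\n", cfg$fst,
            hudson_fst(ds$gene, ds$truth$subpop_labels)))
cat(sprintf("MAF spectrum: %.3f - %.3f (median %.3f)\n",
            min(maf), max(maf), median(maf)))
cat(sprintf("gene model: %d genes over %d SNPs; %d pathways\n",
            nrow(gm), cfg$n_snps, length(pw)))
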