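#!/usr/bin/env Rscript
# Stage 6 -- gene-based statistics and pathway enrichment.
#
# Annotates the fused SNPs to genes by coordinate overlap, computes
# VEGAS-style Monte-Carlo gene-based p-values (cohort-LD null, corrects
# gene-size bias) for the genetic component of the strongest significant
# pair, selects dominant genes at p < 0.05, and tests pathway enrichment
# by the hypergeometric tail with BH FDR.

suppressPackageStartupMessages(library(parafuse))

inp <- "results/study/01_input"
qc <- "results/study/02_qc"
fus <- "results/study/03_fusion"
assoc <- "results/study/05_association"
out <- "results/study/06_pathways"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

snps <- read_tsv(file.path(qc, "fusion_snps.tsv"))
X_gene <- as.matrix(read_tsv(file.path(qc, "fusion_dosages.tsv"))[, -1])
src <- read_tsv(file.path(fus, "gene_sources.tsv"))
pairs <- read_tsv(file.path(assoc, "pair_tests.tsv"))

gene_model <- read_gene_bed(file.path(inp, "genes.bed"))
ann <- annotate_snps_to_genes(snps, gene_model)
cat(sprintf("annotation: %d assignments over %d genes; %d SNPs intergenic\n",
            nrow(ann$assignments), length(unique(ann$assignments$gene)),
            length(ann$unassigned)))

sig <- pairs[!is.na(pairs$significant) & pairs$significant, ]
comp <- if (nrow(sig) > 0) sig$gene[which.min(sig$p)] else 1L
cat(sprintf("gene-based tests on genetic component G%d\n", comp))
snp_p <- component_snp_pvalues(src[[paste0("G", comp)]])
names(snp_p) <- snps$id

genes <- sort(unique(ann$assignments$gene))
seeds <- with(list(), {set.seed(61); sample.int(1e8, length(genes))})
gene_tab <- do.call(rbind, lapply(seq_along(genes), function(gi) {
  ids <- ann$assignments$snp[ann$assignments$gene == genes[gi]]
  jj <- match(ids, snps$id)
  Sigma <- suppressWarnings(cor(X_gene[, jj, drop = FALSE]))
  Sigma[is.na(Sigma)] <- 0
  diag(Sigma) <- 1
  gt <- gene_based_test(snp_p[jj], Sigma, n_sims = 10000, seed = seeds[gi])
  data.frame(gene = genes[gi], n_snps = length(jj), T = gt$T, p = gt$p)
}))
write_tsv(gene_tab, file.path(out, "gene_tests.tsv"))
cat(sprintf("gene-size check: Spearman rho(gene p, SNP count) = %.3f\n",
            cor(gene_tab$p, gene_tab$n_snps, method = "spearman")))

selected <- select_component_genes(setNames(gene_tab$p, gene_tab$gene),
                                   alpha = 0.05)
cat(sprintf("dominant genes (p < 0.05): %d of %d\n", length(selected),
            nrow(gene_tab)))
writeLines(selected, file.path(out, "selected_genes.txt"))

pathways <- read_gmt(file.path(inp, "pathways.gmt"))
enr <- hypergeometric_enrichment(selected, pathways, genes)
write_tsv(enr, file.path(out, "enrichment.tsv"))
cat(sprintf("enrichment: %d pathways tested, %d with q < 0.05\n",
            nrow(enr), sum(enr$q < 0.05)))
print(head(enr[, c("pathway", "overlap", "p", "q")], 5), row.names = FALSE)
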