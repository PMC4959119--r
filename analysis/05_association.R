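#!/usr/bin/env Rscript
# Stage 5 -- loading-coefficient statistics.
#
# Partial correlations between every genetic x brain loading pair
# (controlling for age, sex, two ancestry axes and group) with Bonferroni
# control at alpha / (K_gene x K_brain); post hoc group-difference t-tests
# with Levene's variance check on the components of significant pairs; and
# exploratory clinical-score correlations controlling for age and sex.

suppressPackageStartupMessages(library(parafuse))

inp <- "results/study/01_input"
qc <- "results/study/02_qc"
fus <- "results/study/03_fusion"
out <- "results/study/05_association"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

covars <- read_tsv(file.path(inp, "covariates.tsv"))
EV <- as.matrix(read_tsv(file.path(qc, "ancestry_axes.tsv"))[, -1])
Ag <- as.matrix(read_tsv(file.path(fus, "gene_loadings.tsv"))[, -1])
Ab <- as.matrix(read_tsv(file.path(fus, "brain_loadings.tsv"))[, -1])

Z <- cbind(age = covars$age, sex = covars$sex, EV, group = covars$group)
pairs <- test_all_pairs(Ag, Ab, Z, alpha = 0.05)
thr <- attr(pairs, "threshold")
sig <- pairs[!is.na(pairs$significant) & pairs$significant, ]
cat(sprintf("pair tests: %d pairs, Bonferroni threshold %.3g, %d significant\n",
            nrow(pairs), thr, nrow(sig)))
for (i in seq_len(nrow(sig))) {
  cat(sprintf("  S%d-G%d: r = %.2f, p = %.1g\n", sig$brain[i], sig$gene[i],
              sig$r[i], sig$p[i]))
}
write_tsv(pairs, file.path(out, "pair_tests.tsv"))

gd_g <- group_difference_tests(Ag, covars$group)
gd_b <- group_difference_tests(Ab, covars$group)
write_tsv(gd_g, file.path(out, "group_diff_gene.tsv"))
write_tsv(gd_b, file.path(out, "group_diff_brain.tsv"))
for (i in unique(sig$gene)) {
  cat(sprintf("  group diff G%d: t = %.2f, p = %.3g (Levene p = %.2f)\n",
              i, gd_g$t[i], gd_g$p[i], gd_g$levene_p[i]))
}
for (i in unique(sig$brain)) {
  cat(sprintf("  group diff S%d: t = %.2f, p = %.3g (Levene p = %.2f)\n",
              i, gd_b$t[i], gd_b$p[i], gd_b$levene_p[i]))
}

clin <- clinical_correlations(Ab, covars[grep("_score$", names(covars))],
                              cbind(age = covars$age, sex = covars$sex))
nsig <- sum(clin$significant)
cat(sprintf("clinical correlations (exploratory, p < 0.05 uncorrected): %d of %d\n",
            nsig, nrow(clin)))
best <- clin[which.min(clin$p_uncorrected), ]
cat(sprintf("  strongest: %s vs S%d, r = %.2f, p = %.3g\n", best$score,
            best$component, best$r, best$p_uncorrected))
write_tsv(clin, file.path(out, "clinical_correlations.tsv"))
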