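# SNP->gene annotation, the Monte-Carlo gene-based test, dominant-gene
# selection, and hypergeometric enrichment with BH FDR.

test_that("coordinate annotation is inclusive and matches brute force", {
  genes <- data.frame(symbol = c("GA", "GB", "GC", "GD", "GE"),
                      chrom = c(1, 1, 1, 2, 2),
                      start = c(100, 250, 240, 50, 500),
                      end = c(200, 400, 320, 120, 700))
  set.seed(1)
  snps <- data.frame(id = paste0("s", 1:20),
                     chrom = rep(c(1, 2), each = 10),
                     pos = c(sort(sample(80:450, 10)),
                             sort(sample(40:750, 10))),
                     a1 = "A", a2 = "G")
  ann <- annotate_snps_to_genes(snps, genes)
  # brute-force oracle over all SNP x gene pairs
  oracle <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    sel <- genes$chrom == snps$chrom[i] & genes$start <= snps$pos[i] &
      snps$pos[i] <= genes$end
    if (!any(sel)) return(NULL)
    data.frame(snp = snps$id[i], gene = genes$symbol[sel])
  }))
  expect_equal(ann$assignments[order(ann$assignments$snp,
                                     ann$assignments$gene), ],
               oracle[order(oracle$snp, oracle$gene), ],
               ignore_attr = TRUE)
  expect_setequal(ann$unassigned, setdiff(snps$id, oracle$snp))

  # boundary semantics: a SNP exactly at start is assigned
  b <- annotate_snps_to_genes(
    data.frame(id = "x", chrom = 1, pos = 250, a1 = "A", a2 = "G"), genes)
  expect_true(all(c("GB", "GC") %in% b$assignments$gene))
  # chr-prefix normalisation
  c1 <- annotate_snps_to_genes(
    data.frame(id = "y", chrom = "chr1", pos = 150, a1 = "A", a2 = "G"),
    genes)
  expect_equal(c1$assignments$gene, "GA")
})

test_that("component weights convert to scale-invariant two-sided p-values", {
  set.seed(2)
  w <- rnorm(200)
  p <- component_snp_pvalues(w)
  expect_equal(unname(p[which.min(abs(w - mean(w)))]),
               2 * pnorm(-abs((w - mean(w)) / sd(w))[which.min(abs(w - mean(w)))]))
  expect_equal(p, component_snp_pvalues(w * 37.5))
  # a weight ~1.96 SD from the mean sits near p = 0.05 (appending the
  # point itself shifts the standardisation slightly)
  z196 <- mean(w) + 1.96 * sd(w)
  p2 <- component_snp_pvalues(c(w, z196))
  expect_gt(unname(p2[201]), 0.04)
  expect_lt(unname(p2[201]), 0.06)
  expect_error(component_snp_pvalues(rep(2, 10)), "variance")
})

test_that("gene-based test reproduces its analytic degeneracies", {
  g1 <- gene_based_test(0.03, matrix(1, 1, 1), n_sims = 20000, seed = 1)
  expect_lt(abs(g1$p - 0.03), 3 * g1$se)

  m <- 5
  gLD <- gene_based_test(rep(0.03, m), matrix(1, m, m), n_sims = 20000,
                         seed = 2)
  expect_lt(abs(gLD$p - 0.03), 3 * gLD$se)

  set.seed(3)
  p_in <- runif(6, 0.05, 0.9)
  gI <- gene_based_test(p_in, diag(6), n_sims = 20000, seed = 3)
  closed <- pchisq(sum(qchisq(1 - p_in, 1)), df = 6, lower.tail = FALSE)
  expect_lt(abs(gI$p - closed), 3 * gI$se)

  # adaptive escalation kicks in for extreme statistics
  gx <- gene_based_test(rep(1e-6, 3), diag(3), n_sims = 1000, seed = 4,
                        max_sims = 50000)
  expect_equal(gx$n_sims, 50000)
  expect_error(gene_based_test(numeric(0)), "no SNP")
  expect_error(gene_based_test(c(0.5, 0.5), matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semi-definite")
})

test_that("null gene p-values are uniform and independent of gene size", {
  # a single 500-gene draw carries Spearman sampling error ~0.045, so the
  # size-independence statistic is summarised over three independent draws
  stats_by_draw <- vapply(5:7, function(ms) {
    set.seed(ms)
    n_genes <- 500
    sizes <- sample(1:20, n_genes, replace = TRUE)
    gene_p <- vapply(seq_len(n_genes), function(g) {
      m <- sizes[g]
      rho <- runif(1, 0, 0.7)
      Sigma <- matrix(rho, m, m); diag(Sigma) <- 1
      # null SNP p-values carrying the same LD structure as the reference
      z <- drop(matrix(rnorm(m), 1, m) %*% chol(Sigma))
      p_snp <- 2 * pnorm(-abs(z))
      gene_based_test(p_snp, Sigma, n_sims = 2000, seed = 1000 + g)$p
    }, numeric(1))
    c(ks = suppressWarnings(stats::ks.test(gene_p, "punif")$p.value),
      rho = abs(cor(gene_p, sizes, method = "spearman")))
  }, numeric(2))
  expect_gt(median(stats_by_draw["ks", ]), 0.01)
  expect_lt(median(stats_by_draw["rho", ]), 0.1)
})

test_that("dominant genes are selected by strict p < alpha ascending", {
  p <- c(a = 0.049, b = 0.051, c = 0.001, d = 1, e = 0.05)
  sel <- select_component_genes(p, 0.05)
  expect_equal(sel, c("c", "a"))
  expect_equal(select_component_genes(c(x = 1, y = 1)), character(0))
  expect_length(select_component_genes(p, 0.2), sum(p < 0.2))
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  bg10 <- paste0("g", 1:10)
  res_all <- hypergeometric_enrichment(bg10, list(pw = bg10), bg10)
  expect_equal(res_all$p, 1)

  bg20 <- paste0("g", 1:20)
  res <- hypergeometric_enrichment(bg20[1:5], list(pw = bg20[1:5]), bg20)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # N=10, K=4, n=3: tails by full enumeration of all C(10,3) draws
  bg <- paste0("g", 1:10)
  pw <- bg[1:4]
  draws <- combn(10, 3)
  for (query_hits in 1:3) {
    qg <- c(bg[seq_len(query_hits)], bg[10:(10 - (3 - query_hits) + 1)])
    qg <- unique(qg)[1:3]
    k <- length(intersect(qg, pw))
    res_q <- hypergeometric_enrichment(qg, list(pw = pw), bg)
    enum <- mean(apply(draws, 2, function(d) sum(d <= 4) >= k))
    expect_equal(res_q$p, enum, tolerance = 1e-12)
  }
  expect_error(hypergeometric_enrichment(c("g1", "zz"), list(pw = pw), bg),
               "absent")
  # pathways with no overlap are not tested
  res0 <- hypergeometric_enrichment(bg[1:2],
                                    list(a = bg[1:3], b = bg[9:10]), bg)
  expect_equal(res0$pathway, "a")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  p <- runif(50)
  q <- bh_fdr(p)
  # oracle: q_(i) = min_{j>=i} p_(j) m / j in sorted order
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(q[o], pmin(q_sorted, 1))
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= p))
})
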