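# Variant QC, exact HWE, LD pruning, stratification PCA and the logistic
# pre-filter.

test_that("variant filters remove by call rate, MAF and HWE in order", {
  set.seed(1)
  n <- 60
  D <- cbind(
    mono = rep(0, n),                         # MAF 0 -> MAF filter
    sparse = c(rep(NA, 8), rbinom(n - 8, 2, 0.3)),  # 13% missing
    good = rbinom(n, 2, 0.4),
    hwe_bad = rep(1, n))                      # all hets: gross HWE violation
  snp <- data.frame(id = colnames(D), chrom = 1L, pos = 1:4 * 100L,
                    a1 = "A", a2 = "G")
  G <- genotype_matrix(D, snp, data.frame(id = paste0("i", 1:n),
                                          group = rep(0, n)))
  res <- filter_variants(G, min_call_rate = 0.95, min_maf = 0.01,
                         hwe_alpha = 1e-6)
  expect_equal(res$report$removed_ids$call_rate, "sparse")
  expect_equal(res$report$removed_ids$maf, "mono")
  expect_equal(res$report$removed_ids$hwe, "hwe_bad")
  expect_equal(res$genotypes$snp_records$id, "good")
  expect_equal(sum(res$report$removed) + length(res$report$retained_ids),
               res$report$n_input)
})

test_that("HWE is tested in controls only", {
  n <- 80
  # controls in HWE, cases wildly out of HWE
  ctrl <- c(rep(0, 18), rep(1, 24), rep(2, 8))   # p = 0.4-ish, near HWE
  case <- rep(1, 30)
  D <- matrix(c(ctrl, case), ncol = 1)
  snp <- data.frame(id = "s1", chrom = 1L, pos = 100L, a1 = "A", a2 = "G")
  G <- genotype_matrix(D, snp,
                       data.frame(id = paste0("i", 1:n),
                                  group = rep(c(0, 1), c(50, 30))))
  res <- filter_variants(G, hwe_alpha = 0.05)
  expect_equal(res$genotypes$snp_records$id, "s1")  # survives: controls OK
})

test_that("exact HWE test matches full enumeration and its degeneracies", {
  expect_equal(hwe_exact_test(21, 30, 9), hwe_enum_oracle(21, 30, 9))
  expect_equal(hwe_exact_test(25, 50, 25), hwe_enum_oracle(25, 50, 25))
  expect_equal(hwe_exact_test(25, 50, 25), 1)      # modal het count
  expect_equal(hwe_exact_test(60, 0, 0), 1)        # monomorphic
  expect_equal(hwe_exact_test(0, 0, 60), 1)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  # random cases against the oracle
  set.seed(7)
  for (i in 1:25) {
    cnt <- rmultinom(1, 70, c(0.35, 0.45, 0.2))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]))
  }
})

test_that("exact HWE agrees with the chi-square approximation when counts are large", {
  cases <- list(c(360, 480, 160), c(250, 500, 250), c(420, 430, 150))
  for (cnt in cases) {
    n <- sum(cnt)
    p <- (2 * cnt[3] + cnt[2]) / (2 * n)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    expect_true(all(expd >= 20))
    chi <- sum((cnt - expd)^2 / expd)
    p_chi <- pchisq(chi, df = 1, lower.tail = FALSE)
    p_ex <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
    expect_lt(abs(log10(p_ex) - log10(p_chi)), 0.2)
  }
})

test_that("LD pruning keeps one of a duplicated pair and all independent SNPs", {
  set.seed(3)
  n <- 100
  x <- rbinom(n, 2, 0.4)
  D <- cbind(a = x, b = x, c = rbinom(n, 2, 0.3), d = rbinom(n, 2, 0.2))
  snp <- data.frame(id = colnames(D), chrom = 1L, pos = 1:4 * 50L,
                    a1 = "A", a2 = "G")
  G <- genotype_matrix(D, snp, NULL)
  kept <- ld_prune(G, window_snps = 4, step_snps = 2, r2_max = 0.7)
  expect_equal(sum(c("a", "b") %in% kept), 1)
  expect_true(all(c("c", "d") %in% kept))

  set.seed(8)
  Dind <- sapply(1:10, function(i) rbinom(200, 2, runif(1, 0.2, 0.5)))
  colnames(Dind) <- paste0("v", 1:10)
  Gind <- genotype_matrix(Dind, data.frame(id = colnames(Dind), chrom = 1L,
                                           pos = 1:10 * 10L, a1 = "A",
                                           a2 = "G"), NULL)
  expect_length(ld_prune(Gind, 5, 2, 0.7), 10)
})

test_that("pruning matches the greedy oracle and its r2 post-condition", {
  set.seed(11)
  for (case in 1:6) {
    n <- 120
    p <- 10
    base <- matrix(rbinom(n * p, 2, 0.4), n, p)
    # plant correlated pairs by copying with small perturbation
    base[, 4] <- base[, 3]
    flip <- sample(n, 6)
    base[flip, 4] <- 2 - base[flip, 4]
    base[, 9] <- base[, 7]
    colnames(base) <- paste0("s", 1:p)
    G <- genotype_matrix(base, data.frame(id = colnames(base), chrom = 1L,
                                          pos = 1:p * 10L, a1 = "A",
                                          a2 = "G"), NULL)
    for (w in c(4, 6, 10)) {
      kept <- ld_prune(G, window_snps = w, step_snps = 2, r2_max = 0.7)
      oracle <- greedy_prune_oracle(base, rep(1, p), w, 2, 0.7)
      expect_equal(kept, colnames(base)[oracle])
      # exhaustive post-condition over every window position
      kept_idx <- which(colnames(base) %in% kept)
      for (s in seq(1, p, by = 2)) {
        win <- intersect(s:(s + w - 1), kept_idx)
        if (length(win) < 2) next
        R2 <- cor(base[, win])^2
        diag(R2) <- 0
        expect_lte(max(R2), 0.7)
      }
    }
  }
})

test_that("EIGENSTRAT PCA separates subpopulations and matches an SVD oracle", {
  ds <- generate_linked_dataset(synthetic_config(
    n_subjects = 200, n_snps = 1000, grid_dims = c(8, 8, 8),
    k_gene = 0, k_brain = 1, linked_pairs = list(), fst = 0.1, seed = 31))
  G <- ds$genotypes
  pca <- eigenstrat_pca(G, 5)
  r <- cor(pca$eigenvectors[, 1], ds$truth$subpop_labels)
  expect_gt(abs(r), 0.9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_equal(unname(colSums(pca$eigenvectors^2)), rep(1, 5))

  # algebraic check: axes match the left singular vectors of the
  # normalised matrix, up to sign
  D <- G$dosages
  n <- nrow(D)
  p_hat <- (1 + colSums(D)) / (2 + 2 * n)
  M <- sweep(sweep(D, 2, colMeans(D), "-"), 2, sqrt(p_hat * (1 - p_hat)), "/")
  sv <- svd(M, nu = 5, nv = 0)
  for (k in 1:5) {
    expect_equal(abs(sum(sv$u[, k] * pca$eigenvectors[, k])), 1,
                 tolerance = 1e-6)
  }
})

test_that("a homogeneous population shows no dominant axis", {
  ds <- generate_linked_dataset(synthetic_config(
    n_subjects = 150, n_snps = 800, grid_dims = c(8, 8, 8),
    k_gene = 0, k_brain = 1, linked_pairs = list(), fst = 0,
    ld_within_r = 0, seed = 32))
  pca <- eigenstrat_pca(ds$genotypes, 5)
  ev <- pca$eigenvalues[pca$eigenvalues > 1e-10]
  expect_lt(ev[1] / mean(ev), 2)
})

test_that("ancestry axes are selected by ANOVA against ethnicity", {
  set.seed(5)
  n <- 100
  labels <- rep(0:1, each = n / 2)
  EV <- matrix(rnorm(n * 4), n, 4)
  EV[, 2] <- labels + rnorm(n, sd = 0.1)       # strongly associated
  EV[, 4] <- labels + rnorm(n, sd = 0.5)       # weakly associated
  sel <- select_ancestry_axes(EV, labels, n_keep = 2)
  expect_equal(sel[1], 2)
  expect_true(all(sel %in% c(2, 4)))

  expect_warning(empty <- select_ancestry_axes(EV, rep("eur", n)), "single")
  expect_length(empty, 0)

  perfect <- cbind(labels, matrix(rnorm(n * 2), n, 2))
  expect_equal(select_ancestry_axes(perfect, labels, 1), 1)
})

test_that("covariate regression matches the normal-equations oracle", {
  set.seed(13)
  M <- matrix(rnorm(20 * 5), 20, 5)
  Z <- matrix(rnorm(20 * 2), 20, 2)
  R <- regress_out_covariates(M, Z)
  X <- cbind(1, Z)
  R_oracle <- M - X %*% solve(t(X) %*% X) %*% t(X) %*% M
  expect_equal(R, R_oracle, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(cbind(1, Z), R))), 1e-8)

  # column equal to a covariate residualises to zero
  M2 <- cbind(Z[, 1], rnorm(20))
  expect_equal(max(abs(regress_out_covariates(M2, Z)[, 1])), 0,
               tolerance = 1e-12)
  # orthogonal covariate leaves a column unchanged up to mean removal
  x <- rnorm(20)
  zo <- qr.resid(qr(cbind(1, x)), rnorm(20))
  Rx <- regress_out_covariates(cbind(x), cbind(zo))
  expect_equal(Rx[, 1], x - mean(x), tolerance = 1e-10)

  expect_error(regress_out_covariates(M, cbind(Z, Z[, 1])), "rank")
})

test_that("logistic prefilter retains by p < alpha and flags degenerate SNPs", {
  set.seed(17)
  n <- 300
  group <- rbinom(n, 1, 0.4)
  covars <- cbind(age = runif(n, 12, 18), sex = rbinom(n, 1, 0.5))
  D <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  D[, 1] <- group * 2                       # perfect separation
  D[, 2] <- 1                               # constant
  colnames(D) <- paste0("s", 1:40)
  expect_warning(
    res <- logistic_prefilter(D, group, covars, alpha = 0.1),
    "constant")
  expect_true("s2" %in% res$flagged)
  expect_false("s2" %in% res$retained)
  # separated SNP either flagged or resolved by the penalised fall-back,
  # never retained through an unstable Wald test
  expect_true("s1" %in% res$flagged || !is.na(res$p["s1"]))
  # retention rule is the strict threshold
  expect_equal(sort(res$retained),
               sort(names(which(res$p < 0.1))))
})

test_that("null prefilter p-values are uniform and retention is near alpha", {
  set.seed(23)
  n <- 500
  group <- rbinom(n, 1, 0.32)
  covars <- cbind(age = runif(n, 12, 18), sex = rbinom(n, 1, 0.5))
  D <- matrix(rbinom(n * 2000, 2, runif(2000, 0.1, 0.5)[rep(1:2000, each = n)]),
              n, 2000)
  colnames(D) <- paste0("s", 1:2000)
  res <- logistic_prefilter(D, group, covars, alpha = 0.1)
  p <- res$p[!is.na(res$p)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(length(res$retained) / length(p) - 0.10), 0.02)
})

test_that("stratification correction halves genotype-subpopulation correlation", {
  ds <- generate_linked_dataset(synthetic_config(
    n_subjects = 200, n_snps = 600, grid_dims = c(8, 8, 8),
    k_gene = 0, k_brain = 1, linked_pairs = list(), fst = 0.1, seed = 41))
  D <- ds$gene
  sub <- ds$truth$subpop_labels
  pca <- eigenstrat_pca(ds$genotypes, 5)
  axes <- select_ancestry_axes(pca$eigenvectors, sub, 2)
  resid <- regress_out_covariates(D, pca$eigenvectors[, axes, drop = FALSE])
  before <- mean(abs(suppressWarnings(cor(D, sub))), na.rm = TRUE)
  after <- mean(abs(suppressWarnings(cor(resid, sub))), na.rm = TRUE)
  expect_lt(after, 0.5 * before)
})
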