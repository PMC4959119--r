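# The coupled (parallel) ICA optimisation.

latent_pair <- function(n = 120, snps = 400, grid = c(10, 10, 10),
                        r = 0.6, noise = 0.5, seed = 1) {
  generate_linked_dataset(synthetic_config(
    n_subjects = n, n_snps = snps, grid_dims = grid, k_gene = 3,
    k_brain = 2, linked_pairs = list(c(1, 1, r)), group_effect = 0,
    noise_sd_gene = noise, noise_sd_brain = noise, latent_mode = TRUE,
    seed = seed))
}

test_that("lambda = 0 reproduces two independent Infomax runs bit-for-bit", {
  ds <- latent_pair(n = 60, snps = 200, grid = c(8, 8, 8), seed = 2)
  fit <- run_para_ica(ds$gene, ds$brain, 3, 2, lambda = 0,
                      max_epochs = 60, seed = 9)
  seeds <- parafuse:::derive_seeds(9, 2)
  wg <- pca_whiten(ds$gene, 3)
  wb <- pca_whiten(ds$brain, 2)
  ig <- run_infomax(wg$whitened, max_epochs = 60, seed = seeds[1])
  ib <- run_infomax(wb$whitened, max_epochs = 60, seed = seeds[2])
  expect_identical(fit$gene_W, ig$W)
  expect_identical(fit$brain_W, ib$W)
})

test_that("a single coupling step strictly increases the target corr^2", {
  ds <- latent_pair(n = 80, snps = 200, grid = c(8, 8, 8), seed = 3)
  wg <- pca_whiten(ds$gene, 3)
  wb <- pca_whiten(ds$brain, 2)
  set.seed(5)
  Wg <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
  Wb <- diag(2) + 0.1 * matrix(rnorm(4), 2, 2)
  Winv_g <- solve(Wg); Winv_b <- solve(Wb)
  A_g <- wg$dewhitening %*% Winv_g
  A_b <- wb$dewhitening %*% Winv_b
  R <- cor(A_g, A_b)
  ij <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1, ]
  r0 <- R[ij[1], ij[2]]
  cs <- parafuse:::coupling_step(Winv_g, Winv_b, wg$dewhitening,
                                 wb$dewhitening, ij[1], ij[2],
                                 eta_rel = 1e-3)
  expect_true(cs$moved)
  expect_gt(cs$r^2, r0^2)
  # finite-difference check: realised gain matches a fresh evaluation
  A_g2 <- wg$dewhitening %*% cs$Winv_g
  A_b2 <- wb$dewhitening %*% cs$Winv_b
  expect_equal(cor(A_g2[, ij[1]], A_b2[, ij[2]]), cs$r, tolerance = 1e-12)
})

test_that("Para-ICA recovers the planted linked pair", {
  rs <- vapply(1:3, function(s) {
    ds <- latent_pair(r = 0.6, seed = s)
    fit <- run_para_ica(ds$gene, ds$brain, 3, 2, max_epochs = 300, seed = s)
    mg <- match_components(fit$gene_model$sources, ds$truth$gene_sources)
    mb <- match_components(fit$brain_model$sources, ds$truth$brain_sources)
    gi <- which(mg$permutation == 1)
    bi <- which(mb$permutation == 1)
    abs(cor(fit$gene_model$loadings[, gi], fit$brain_model$loadings[, bi]))
  }, numeric(1))
  expect_lt(abs(median(rs) - 0.6), 0.15)
})

test_that("entropy terms are non-decreasing over accepted epochs", {
  ds <- latent_pair(n = 80, snps = 250, grid = c(8, 8, 8), seed = 6)
  fit <- run_para_ica(ds$gene, ds$brain, 3, 2, max_epochs = 150, seed = 4)
  tr <- fit$objective_trace
  # every accepted Infomax epoch keeps its entropy term at or above the
  # state it started from (coupling may lower the baseline in between;
  # those moves are traded against the coupling term, not accepted epochs)
  ok_g <- tr$accepted_gene & !is.na(tr$entropy_gene_pre)
  ok_b <- tr$accepted_brain & !is.na(tr$entropy_brain_pre)
  expect_true(all(tr$entropy_gene[ok_g] >=
                    tr$entropy_gene_pre[ok_g] * (1 + 1e-9) - 1e-12))
  expect_true(all(tr$entropy_brain[ok_b] >=
                    tr$entropy_brain_pre[ok_b] * (1 + 1e-9) - 1e-12))
  # and with coupling disabled the accepted entropy sequence is monotone
  fit0 <- run_para_ica(ds$gene, ds$brain, 3, 2, lambda = 0,
                       max_epochs = 150, seed = 4)
  tr0 <- fit0$objective_trace
  eg <- tr0$entropy_gene[tr0$accepted_gene]
  expect_true(all(diff(eg) >= -1e-9 * abs(eg[-length(eg)]) - 1e-12))
  # linked-pair correlations recomputable from stored loadings
  for (i in seq_len(nrow(fit$linked_pairs))) {
    expect_equal(fit$linked_pairs$r[i],
                 cor(fit$gene_model$loadings[, fit$linked_pairs$gene[i]],
                     fit$brain_model$loadings[, fit$linked_pairs$brain[i]]),
                 tolerance = 1e-8)
  }
})

test_that("recovered link correlation is non-decreasing in lambda", {
  meds <- vapply(c(0, 1, 2), function(lam) {
    rs <- vapply(1:3, function(s) {
      ds <- latent_pair(n = 100, snps = 300, grid = c(8, 8, 8), r = 0.45,
                        noise = 0.8, seed = 20 + s)
      fit <- run_para_ica(ds$gene, ds$brain, 3, 2, lambda = lam,
                          max_epochs = 200, seed = s)
      mg <- match_components(fit$gene_model$sources, ds$truth$gene_sources)
      mb <- match_components(fit$brain_model$sources, ds$truth$brain_sources)
      gi <- which(mg$permutation == 1)
      bi <- which(mb$permutation == 1)
      abs(cor(fit$gene_model$loadings[, gi], fit$brain_model$loadings[, bi]))
    }, numeric(1))
    median(rs)
  }, numeric(1))
  expect_true(all(diff(meds) >= -0.02))   # monotone up to matching jitter
})

test_that("coupling does not degrade source recovery", {
  degrade <- vapply(1:3, function(s) {
    ds <- latent_pair(seed = 40 + s)
    rec <- function(lam) {
      fit <- run_para_ica(ds$gene, ds$brain, 3, 2, lambda = lam,
                          max_epochs = 250, seed = s)
      mg <- match_components(fit$gene_model$sources, ds$truth$gene_sources)
      mb <- match_components(fit$brain_model$sources, ds$truth$brain_sources)
      median(c(mg$matched_abs, mb$matched_abs))
    }
    rec(0) - rec(1)
  }, numeric(1))
  expect_lt(median(degrade), 0.05)
})

test_that("mismatched subject counts are rejected", {
  ds <- latent_pair(n = 30, snps = 100, grid = c(8, 8, 8), seed = 1)
  expect_error(run_para_ica(ds$gene[1:20, ], ds$brain, 2, 2),
               "subject counts")
})
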