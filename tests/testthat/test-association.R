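# Partial correlations, the Bonferroni pair table, group differences and
# clinical correlations.

test_that("the published significance arithmetic reproduces at r=0.34 and r=0.31", {
  d1 <- make_exact_partial_r(0.34, 198, 5, seed = 1)
  pc1 <- partial_correlation(d1$x, d1$y, d1$Z)
  expect_equal(pc1$r, 0.34, tolerance = 1e-10)
  expect_equal(pc1$df, 191)
  expect_equal(signif(pc1$p, 1), 1e-6)

  d2 <- make_exact_partial_r(0.31, 198, 5, seed = 2)
  pc2 <- partial_correlation(d2$x, d2$y, d2$Z)
  expect_equal(signif(pc2$p, 1), 1e-5)
})

test_that("partial correlation reduces to Pearson and matches the oracle", {
  set.seed(3)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  pc <- partial_correlation(x, y, NULL)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pc$df, 48)

  for (i in 1:10) {
    n <- 40
    Z <- matrix(rnorm(n * 3), n, 3)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * Z[, 1]
    pc <- partial_correlation(x, y, Z)
    or <- partial_cor_oracle(x, y, Z)
    expect_equal(pc$r, or$r, tolerance = 1e-10)
    expect_equal(pc$p, or$p, tolerance = 1e-10)
  }
  expect_error(partial_correlation(rep(1, 20), rnorm(20), NULL), "variance")
})

test_that("p-values are invariant under affine rescaling", {
  set.seed(4)
  n <- 60
  Z <- matrix(rnorm(n * 2), n, 2)
  x <- rnorm(n); y <- 0.3 * x + rnorm(n)
  base <- partial_correlation(x, y, Z)
  scaled <- partial_correlation(5 * x - 2, -0.1 * y + 7,
                                sweep(Z, 2, c(2, -3), "*"))
  expect_equal(abs(scaled$r), abs(base$r), tolerance = 1e-10)
  expect_equal(scaled$p, base$p, tolerance = 1e-10)
})

test_that("the pair table applies the K_gene x K_brain Bonferroni threshold", {
  set.seed(5)
  n <- 198
  Ag <- matrix(rnorm(n * 14), n, 14)
  Ab <- matrix(rnorm(n * 9), n, 9)
  # plant one strong pair
  Ab[, 1] <- 0.5 * Ag[, 1] + sqrt(0.75) * rnorm(n)
  Z <- matrix(rnorm(n * 5), n, 5)
  tab <- test_all_pairs(Ag, Ab, Z, alpha = 0.05)
  expect_equal(attr(tab, "threshold"), 0.05 / 126)
  expect_equal(nrow(tab), 126)
  expect_true(tab$significant[tab$gene == 1 & tab$brain == 1])
  expect_true(all(tab$significant == (tab$p < 0.05 / 126), na.rm = TRUE))
  expect_equal(tab$df, rep(n - 2 - 5, 126))

  # symmetric under swapping modalities
  tab_sw <- test_all_pairs(Ab, Ag, Z, alpha = 0.05)
  m <- merge(tab, tab_sw, by.x = c("gene", "brain"),
             by.y = c("brain", "gene"))
  expect_equal(m$r.x, m$r.y, tolerance = 1e-12)
  expect_equal(m$p.x, m$p.y, tolerance = 1e-12)
})

test_that("family-wise error stays at or below nominal under the null", {
  set.seed(6)
  n_tab <- 400
  fw <- vapply(seq_len(n_tab), function(i) {
    Ag <- matrix(rnorm(40 * 3), 40, 3)
    Ab <- matrix(rnorm(40 * 3), 40, 3)
    any(test_all_pairs(Ag, Ab, NULL, alpha = 0.05)$significant)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_tab)
  expect_lte(mean(fw), 0.05 + 2 * se)
})

test_that("group tests match hand-computed t and Levene on a toy", {
  x <- c(1, 2, 3)           # control
  y <- c(5, 6, 10)          # patient
  load <- matrix(c(x, y), ncol = 1)
  g <- c(0, 0, 0, 1, 1, 1)
  res <- group_difference_tests(load, g)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # Levene W (centre = mean) by the textbook formula
  adx <- abs(x - mean(x)); ady <- abs(y - mean(y))
  zz <- c(adx, ady)
  W_hand <- (4 / 1) * (3 * (mean(adx) - mean(zz))^2 +
                         3 * (mean(ady) - mean(zz))^2) /
    (sum((adx - mean(adx))^2) + sum((ady - mean(ady))^2))
  expect_equal(res$levene_W, W_hand, tolerance = 1e-12)
  expect_equal(res$mean_control, 2)
  expect_equal(res$mean_patient, 7)

  # identical groups degenerate cleanly
  same <- matrix(rep(c(1, 2, 3), 2), ncol = 1)
  res0 <- group_difference_tests(same, g)
  expect_equal(res0$t, 0)
  expect_equal(res0$levene_W, 0)
})

test_that("group tests agree with car::leveneTest as an independent check", {
  skip_if_not_installed("car")
  set.seed(7)
  load <- matrix(rnorm(60), ncol = 1)
  g <- rep(0:1, c(25, 35))
  res <- group_difference_tests(load, g)
  lt <- car::leveneTest(load[, 1], factor(g), center = mean)
  expect_equal(res$levene_W, lt[1, "F value"], tolerance = 1e-10)
  expect_equal(res$levene_p, lt[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("a planted one-SD group shift is detected at the study sizes", {
  set.seed(8)
  g <- rep(c(0, 1), c(135, 63))
  load <- matrix(rnorm(198) + g * 1, ncol = 1)
  res <- group_difference_tests(load, g)
  expect_lt(res$p, 0.001)
  expect_error(group_difference_tests(load, rep(0, 198)), "two groups")
})

test_that("clinical correlations flag the constructed score first", {
  set.seed(9)
  n <- 150
  load <- matrix(rnorm(n * 4), n, 4)
  Z <- cbind(age = runif(n, 12, 18), sex = rbinom(n, 1, 0.5))
  scores <- data.frame(
    built = 0.6 * load[, 2] + 0.8 * rnorm(n),
    unrelated = rnorm(n))
  res <- clinical_correlations(load, scores, Z)
  best <- res[which.min(res$p_uncorrected), ]
  expect_equal(best$score, "built")
  expect_equal(best$component, 2)
  expect_true(all(res$exploratory))
  expect_equal(res$significant, res$p_uncorrected < 0.05)
})

test_that("null clinical correlations are uncorrected-significant at ~5%", {
  set.seed(10)
  n <- 120
  load <- matrix(rnorm(n * 2), n, 2)
  Z <- cbind(runif(n, 12, 18), rbinom(n, 1, 0.5))
  scores <- as.data.frame(matrix(rnorm(n * 150), n, 150))
  res <- clinical_correlations(load, scores, Z)
  rate <- mean(res$significant)
  expect_lt(abs(rate - 0.05), 0.03)
})

test_that("missing scores are handled pairwise and empty ones skipped", {
  set.seed(11)
  n <- 60
  load <- matrix(rnorm(n * 2), n, 2)
  Z <- cbind(runif(n), rbinom(n, 1, 0.5))
  scores <- data.frame(ok = c(rep(NA, 10), rnorm(n - 10)),
                       gone = rep(NA_real_, n))
  w <- capture_warnings(res <- clinical_correlations(load, scores, Z))
  expect_true(length(w) >= 1 && all(grepl("skipped", w)))
  expect_true(all(res$score == "ok"))
  expect_equal(unique(res$n), n - 10)
})
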