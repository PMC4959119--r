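# Loading-coefficient statistics: partial correlations with Bonferroni
# control over all component pairs, group-difference tests with Levene's
# variance check, and exploratory clinical correlations.

#' Partial correlation of two vectors given covariates
#'
#' Residualises `x` and `y` on `[intercept, Z]` and returns the Pearson
#' correlation of the residuals with its t statistic
#' `t = r sqrt(df / (1 - r^2))`, `df = n - 2 - q` (`q` covariates), and the
#' two-tailed p from the t distribution.  With empty `Z` this reduces to
#' the plain Pearson correlation with `df = n - 2`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param Z Covariate matrix/data.frame (no intercept column), or `NULL`.
#' @return list(r, t, df, p, n).
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_pf("x and y lengths differ")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    keep <- complete.cases(x, y, Z)
  } else {
    keep <- complete.cases(x, y)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  q <- if (is.null(Z)) 0L else ncol(Z)
  df <- n - 2L - q
  if (df <= 0) stop_pf("nonpositive degrees of freedom (n = %d, q = %d)", n, q)
  if (q > 0) {
    Zk <- cbind(1, Z[keep, , drop = FALSE])
    qz <- qr(Zk)
    if (qz$rank < ncol(Zk)) stop_pf("covariates are rank deficient")
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0) stop_pf("zero residual variance")
  r <- sum(x * y) / (sx * sy)
  r <- max(min(r, 1), -1)
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, t = t, df = df, p = 2 * pt(-abs(t), df), n = n)
}

#' Test all genetic x brain loading pairs with Bonferroni control
#'
#' Computes the partial correlation (given `Z`) for every pair of a genetic
#' and a brain loading column and flags pairs with
#' `p < alpha / (K_gene * K_brain)` — the family-wise threshold
#' `0.05 / (9 x 14)` when applied at the study's component counts.
#'
#' @param gene_loadings,brain_loadings subjects x K matrices, same row order.
#' @param Z Covariates (typically age, sex, two ancestry axes, group).
#' @param alpha Family-wise error target.
#' @return data.frame of class `pair_test_table` with columns `gene`,
#'   `brain`, `r`, `t`, `df`, `p`, `significant`; attribute `threshold`.
#' @export
test_all_pairs <- function(gene_loadings, brain_loadings, Z = NULL,
                           alpha = 0.05) {
  Kg <- ncol(gene_loadings); Kb <- ncol(brain_loadings)
  thr <- alpha / (Kg * Kb)
  rows <- vector("list", Kg * Kb)
  idx <- 0L
  for (i in seq_len(Kg)) {
    for (j in seq_len(Kb)) {
      idx <- idx + 1L
      pc <- tryCatch(
        partial_correlation(gene_loadings[, i], brain_loadings[, j], Z),
        error = function(e) NULL)
      rows[[idx]] <- if (is.null(pc)) {
        data.frame(gene = i, brain = j, r = NA_real_, t = NA_real_,
                   df = NA_integer_, p = NA_real_, significant = NA)
      } else {
        data.frame(gene = i, brain = j, r = pc$r, t = pc$t, df = pc$df,
                   p = pc$p, significant = pc$p < thr)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  class(out) <- c("pair_test_table", class(out))
  out
}

#' Group-difference tests on loading columns
#'
#' Per component: pooled-variance two-sample t-test of the loading column
#' between groups, Levene's test for equality of variances (centre = mean,
#' computed as one-way ANOVA of absolute deviations from the group means),
#' and the group means for bar-plot style reporting.  Degenerate columns
#' with zero pooled variance yield `t = 0`, `W = 0`, `p = 1`.
#'
#' @param loadings subjects x K matrix.
#' @param group Binary group vector (0 = control, 1 = patient).
#' @return data.frame: component, t, df, p, levene_W, levene_p,
#'   mean_control, mean_patient.
#' @export
group_difference_tests <- function(loadings, group) {
  group <- as.integer(group)
  tab <- table(group)
  if (length(tab) != 2 || any(tab < 2)) {
    stop_pf("need two groups with at least 2 subjects each")
  }
  g1 <- group == 1L
  do.call(rbind, lapply(seq_len(ncol(loadings)), function(k) {
    x <- loadings[!g1, k]; y <- loadings[g1, k]
    df <- length(x) + length(y) - 2L
    if (var(x) + var(y) == 0) {
      tt <- list(statistic = 0, p.value = if (mean(x) == mean(y)) 1 else 0)
    } else {
      ht <- t.test(x, y, var.equal = TRUE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    adx <- abs(x - mean(x)); ady <- abs(y - mean(y))
    if (var(adx) + var(ady) == 0) {
      lev <- c(W = 0, p = 1)
    } else {
      fit <- anova(lm(c(adx, ady) ~ factor(rep(0:1, c(length(x), length(y))))))
      lev <- c(W = fit[["F value"]][1], p = fit[["Pr(>F)"]][1])
    }
    data.frame(component = k, t = tt$statistic, df = df, p = tt$p.value,
               levene_W = unname(lev["W"]), levene_p = unname(lev["p"]),
               mean_control = mean(x), mean_patient = mean(y))
  }))
}

#' Exploratory clinical-score correlations with loadings
#'
#' Partial correlation of every (clinical score, component loading) pair
#' controlling for age and sex, pairwise-complete, reporting uncorrected p
#' (flagged exploratory) plus whether each pair would survive Bonferroni
#' over the full set.
#'
#' @param loadings subjects x K matrix.
#' @param clinical_scores data.frame/matrix of scores (may contain `NA`).
#' @param Z_age_sex Two-column covariate matrix (age, sex).
#' @param alpha Uncorrected significance threshold.
#' @return data.frame: score, component, n, r, p_uncorrected, significant
#'   (uncorrected), bonferroni_significant, exploratory (always TRUE).
#' @export
clinical_correlations <- function(loadings, clinical_scores, Z_age_sex,
                                  alpha = 0.05) {
  scores <- as.data.frame(clinical_scores)
  rows <- list()
  for (sc in names(scores)) {
    for (k in seq_len(ncol(loadings))) {
      res <- tryCatch(
        partial_correlation(scores[[sc]], loadings[, k], Z_age_sex),
        error = function(e) NULL)
      if (is.null(res)) {
        warn_pf("score %s vs component %d skipped (insufficient data)", sc, k)
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(score = sc, component = k, n = res$n, r = res$r,
                   p_uncorrected = res$p)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(score = character(0), component = integer(0),
                      n = integer(0), r = numeric(0),
                      p_uncorrected = numeric(0), significant = logical(0),
                      bonferroni_significant = logical(0),
                      exploratory = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_uncorrected < alpha
  out$bonferroni_significant <- out$p_uncorrected < alpha / nrow(out)
  out$exploratory <- TRUE
  out
}
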