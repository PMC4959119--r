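# Genotype QC chain: variant filters, exact Hardy-Weinberg test, windowed LD
# pruning, EIGENSTRAT-style PCA with ancestry-axis selection, covariate
# regression, and the logistic pre-filter that selects SNPs entering the
# fusion stage.

#' Construct a genotype matrix container
#'
#' @param dosages subjects x SNPs numeric matrix with entries in \{0,1,2\}
#'   or `NA` for missing (count of the A1/alt allele).
#' @param snp_records data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `a1`, `a2`; one row per SNP, positions strictly increasing within
#'   chromosome.
#' @param sample_records data.frame with at least column `id`; typically also
#'   `age`, `sex`, `group`, `ethnicity`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_records, sample_records = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(snp_records)) {
    stop_pf("dosage columns (%d) != snp_records rows (%d)",
            ncol(dosages), nrow(snp_records))
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop_pf("dosages must be in {0,1,2} or NA")
  for (ch in unique(snp_records$chrom)) {
    p <- snp_records$pos[snp_records$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop_pf("positions not strictly increasing on chromosome %s", ch)
    }
  }
  if (is.null(sample_records)) {
    sample_records <- data.frame(id = paste0("S", seq_len(nrow(dosages))))
  }
  colnames(dosages) <- snp_records$id
  rownames(dosages) <- sample_records$id
  structure(list(dosages = dosages, snp_records = snp_records,
                 sample_records = sample_records),
            class = "genotype_matrix")
}

snp_call_rate <- function(dosages) 1 - colMeans(is.na(dosages))

snp_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the allele counts, the probability
#' of each possible heterozygote count is computed from the hypergeometric-
#' type HWE distribution and the p-value is the sum of probabilities not
#' exceeding that of the observed count.  No mid-p correction.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_pf("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) stop_pf("all genotype counts are zero")
  n_a <- 2 * n_hom_alt + n_het           # minor-ish allele count (alt)
  n_b <- 2 * n_hom_ref + n_het
  n_minor <- min(n_a, n_b)
  # possible het counts share parity with n_minor
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # unnormalised log-probabilities of the conditional distribution:
  # P(het) proportional to n! / (hom_a! het! hom_b!) * 2^het
  lp <- vapply(hets, function(h) {
    hm <- (n_minor - h) / 2          # hom-minor count
    hM <- n - h - hm                 # hom-major count
    h * log(2) - lgamma(hm + 1) - lgamma(h + 1) - lgamma(hM + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) stop_pf("observed het count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality-control filters
#'
#' Applies, in order: call-rate filter, minor-allele-frequency filter, and an
#' exact Hardy-Weinberg test computed in the control group only (subjects
#' with `group == 0`; all subjects if no group column).  Default thresholds
#' are field-standard exome-array values and fully configurable.
#'
#' @param G `genotype_matrix`.
#' @param min_call_rate Minimum per-SNP call rate.
#' @param min_maf Minimum minor allele frequency.
#' @param hwe_alpha HWE exact-test significance cutoff (controls only).
#' @return list(genotypes = filtered `genotype_matrix`, report = `qc_report`
#'   with per-filter removal counts, retained ids and thresholds).
#' @export
filter_variants <- function(G, min_call_rate = 0.95, min_maf = 0.01,
                            hwe_alpha = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  for (th in c(min_call_rate, min_maf, hwe_alpha)) {
    if (th <= 0 || th >= 1) stop_pf("QC thresholds must lie in (0,1)")
  }
  D <- G$dosages
  n_in <- ncol(D)
  alive <- rep(TRUE, n_in)

  fail_call <- snp_call_rate(D) < min_call_rate
  removed_call <- which(alive & fail_call)
  alive[removed_call] <- FALSE

  maf <- snp_maf(D)
  fail_maf <- is.na(maf) | maf < min_maf
  removed_maf <- which(alive & fail_maf)
  alive[removed_maf] <- FALSE

  ctrl <- if ("group" %in% names(G$sample_records)) {
    G$sample_records$group == 0
  } else rep(TRUE, nrow(D))
  removed_hwe <- integer(0)
  for (j in which(alive)) {
    g <- D[ctrl, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) next
    p <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    if (p < hwe_alpha) removed_hwe <- c(removed_hwe, j)
  }
  alive[removed_hwe] <- FALSE

  if (!any(alive)) {
    first <- if (length(removed_call) == n_in) "call rate"
             else if (!any(alive) && length(removed_hwe) > 0 &&
                      sum(!fail_call & !fail_maf) > 0) "HWE"
             else "MAF"
    stop_pf("no SNPs survive QC; filter exhausting the set: %s", first)
  }

  report <- structure(list(
    n_input = n_in,
    removed = c(call_rate = length(removed_call),
                maf = length(removed_maf),
                hwe = length(removed_hwe)),
    removed_ids = list(call_rate = G$snp_records$id[removed_call],
                       maf = G$snp_records$id[removed_maf],
                       hwe = G$snp_records$id[removed_hwe]),
    retained_ids = G$snp_records$id[alive],
    thresholds = c(min_call_rate = min_call_rate, min_maf = min_maf,
                   hwe_alpha = hwe_alpha)), class = "qc_report")

  out <- genotype_matrix(D[, alive, drop = FALSE],
                         G$snp_records[alive, , drop = FALSE],
                         G$sample_records)
  list(genotypes = out, report = report)
}

#' Greedy windowed LD pruning
#'
#' Reproduces PLINK-style `--indep-pairwise` pruning: within a sliding window
#' of `window_snps` SNPs advanced by `step_snps` per chromosome, while any
#' retained pair has squared Pearson dosage correlation above `r2_max`, the
#' pair with the largest r-squared is broken by removing the member with the
#' lower minor allele frequency (tie: the later-positioned SNP).
#'
#' @param G `genotype_matrix`.
#' @param window_snps,step_snps,r2_max Window size, step, and r-squared cap.
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(G, window_snps = 50, step_snps = 5, r2_max = 0.7) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (window_snps < 2) stop_pf("window_snps must be >= 2")
  D <- G$dosages
  maf <- snp_maf(D)
  keep <- rep(TRUE, ncol(D))
  for (ch in unique(G$snp_records$chrom)) {
    idx <- which(G$snp_records$chrom == ch)
    starts <- seq(1L, max(1L, length(idx)), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      win <- win[keep[win]]
      keep <- prune_window(D, win, maf, r2_max, keep)
      if (s + window_snps - 1L >= length(idx)) break
    }
  }
  G$snp_records$id[keep]
}

prune_window <- function(D, win, maf, r2_max, keep) {
  while (length(win) >= 2) {
    R <- suppressWarnings(cor(D[, win, drop = FALSE],
                              use = "pairwise.complete.obs"))
    R[is.na(R)] <- 0
    r2 <- R^2
    diag(r2) <- 0
    if (max(r2) <= r2_max) break
    worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    a <- win[worst[1]]; b <- win[worst[2]]
    drop_snp <- if (isTRUE(maf[a] < maf[b])) a
                else if (isTRUE(maf[b] < maf[a])) b
                else max(a, b)            # tie: later-positioned
    keep[drop_snp] <- FALSE
    win <- win[win != drop_snp]
  }
  keep
}

#' EIGENSTRAT-style principal component analysis of genotypes
#'
#' Each SNP column is centred by its mean dosage (twice the sample allele
#' frequency) and scaled by `sqrt(p (1 - p))` with `p` the smoothed
#' allele-frequency estimate `(1 + allele count) / (2 + 2n)`; missing
#' dosages are mean-imputed after normalisation (set to zero).  Axes are
#' the eigenvectors of the subject x subject covariance of the normalised
#' matrix, unit norm, eigenvalues descending.
#'
#' @param G `genotype_matrix` (no monomorphic SNPs).
#' @param n_axes Number of leading axes to return.
#' @return list(eigenvectors = subjects x n_axes, eigenvalues = all
#'   eigenvalues, descending).
#' @export
eigenstrat_pca <- function(G, n_axes = 10) {
  stopifnot(inherits(G, "genotype_matrix"))
  D <- G$dosages
  n <- nrow(D)
  counts <- colSums(D, na.rm = TRUE)
  n_obs <- colSums(!is.na(D))
  p_hat <- (1 + counts) / (2 + 2 * n_obs)
  mono <- apply(D, 2L, function(x) var(x, na.rm = TRUE)) == 0
  if (any(mono, na.rm = TRUE)) {
    stop_pf("zero-variance SNP after normalization: %s",
            paste(head(G$snp_records$id[which(mono)], 5), collapse = ", "))
  }
  M <- sweep(D, 2L, colMeans(D, na.rm = TRUE), "-")
  M[is.na(M)] <- 0                  # missing -> centred mean (zero)
  M <- sweep(M, 2L, sqrt(p_hat * (1 - p_hat)), "/")
  C <- tcrossprod(M) / ncol(M)
  e <- eigen(C, symmetric = TRUE)
  n_axes <- min(n_axes, n)
  list(eigenvectors = e$vectors[, seq_len(n_axes), drop = FALSE],
       eigenvalues = e$values)
}

#' Select ancestry axes associated with self-reported ethnicity
#'
#' One-way ANOVA of each eigenvector against the ethnicity factor; the
#' `n_keep` axes with smallest p among those with p < 0.05 are returned in
#' order of increasing p (fewer if fewer qualify).
#'
#' @param eigenvectors subjects x axes matrix.
#' @param ethnicity_labels Factor-coercible vector.
#' @param n_keep Number of axes to select.
#' @return Integer vector of axis indices (possibly empty).
#' @export
select_ancestry_axes <- function(eigenvectors, ethnicity_labels, n_keep = 2) {
  f <- factor(ethnicity_labels)
  if (nlevels(f) < 2) {
    warn_pf("single ethnicity level: no ancestry axes selected")
    return(integer(0))
  }
  p <- vapply(seq_len(ncol(eigenvectors)), function(j) {
    fit <- lm(eigenvectors[, j] ~ f)
    av <- suppressWarnings(anova(fit))   # perfect fits are fine here
    av[["Pr(>F)"]][1]
  }, numeric(1))
  qual <- which(p < 0.05)
  qual[order(p[qual])][seq_len(min(n_keep, length(qual)))]
}

#' Regress covariates out of every column of a matrix
#'
#' Replaces each column of `M` by its least-squares residual on
#' `[intercept, covariates]`.
#'
#' @param M Numeric matrix (e.g. dosages or loadings).
#' @param covariates Numeric matrix/data.frame of covariates (no intercept).
#' @return Residual matrix, same dimensions as `M`.
#' @export
regress_out_covariates <- function(M, covariates) {
  M <- as.matrix(M)
  Z <- cbind(intercept = 1, as.matrix(covariates))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    bad <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    stop_pf("rank-deficient covariates: %s", paste(bad, collapse = ", "))
  }
  qr.resid(qrz, M)
}

#' Per-SNP logistic pre-filter on case/control status
#'
#' Fits, for every SNP, a logistic regression of group on
#' `[dosage, covariates]` and retains SNPs whose dosage Wald p-value is below
#' `alpha` (the uncorrected screening threshold).  SNPs whose fit does not
#' converge or shows separation are refit with a Firth-type penalised
#' likelihood; if that is still unstable the SNP is excluded and flagged.
#'
#' @param G_resid subjects x SNPs numeric matrix (typically residualised
#'   dosages) or `genotype_matrix`.
#' @param group Binary 0/1 vector.
#' @param covariates Covariate matrix (age, sex, ancestry axes, ...).
#' @param alpha Retention threshold on the uncorrected p-value.
#' @return list(retained = SNP ids with p < alpha, p = named per-SNP p,
#'   flagged = ids excluded for separation/non-convergence).
#' @export
logistic_prefilter <- function(G_resid, group, covariates, alpha = 0.1) {
  D <- if (inherits(G_resid, "genotype_matrix")) G_resid$dosages else
    as.matrix(G_resid)
  ids <- colnames(D) %||% paste0("snp", seq_len(ncol(D)))
  group <- as.numeric(group)
  stopifnot(all(group %in% c(0, 1)))
  Z <- as.matrix(covariates)
  p <- setNames(rep(NA_real_, ncol(D)), ids)
  flagged <- character(0)
  for (j in seq_len(ncol(D))) {
    x <- D[, j]
    ok <- !is.na(x)
    if (var(x[ok]) == 0) {
      warn_pf("constant dosage column %s excluded from prefilter", ids[j])
      flagged <- c(flagged, ids[j])
      next
    }
    X <- cbind(dosage = x[ok], Z[ok, , drop = FALSE])
    fit_p <- wald_p_logistic(group[ok], X)
    if (is.na(fit_p)) {
      fit_p <- firth_wald_p(group[ok], cbind(1, X))
      if (is.na(fit_p)) {
        flagged <- c(flagged, ids[j])
        next
      }
    }
    p[j] <- fit_p
  }
  retained <- ids[!is.na(p) & p < alpha]
  list(retained = retained, p = p, flagged = flagged)
}

# Wald p for the first column of X in a logistic glm; NA on non-convergence
# or separation.
wald_p_logistic <- function(y, X) {
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ X, family = binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (warned || !fit$converged) return(NA_real_)
  s <- summary(fit)$coefficients
  row <- grep("dosage", rownames(s))[1]
  if (is.na(row)) return(NA_real_)
  s[row, "Pr(>|z|)"]
}

# Firth-penalised logistic regression (Jeffreys prior); returns the Wald p
# of the second coefficient (first column after intercept).
firth_wald_p <- function(y, X, max_iter = 50, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    XW <- X * w
    I <- crossprod(X, XW)
    Iinv <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(Iinv)) return(NA_real_)
    h <- rowSums((X %*% Iinv) * XW)   # diag of the hat matrix
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(Iinv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) {
      se <- sqrt(diag(Iinv))
      z <- b[2] / se[2]
      return(2 * pnorm(-abs(z)))
    }
  }
  NA_real_
}
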