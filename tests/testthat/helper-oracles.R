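# Independent oracles used across the suite.  Each is deliberately written
# as a direct, naive translation of the defining rule, separate from the
# package's implementation path.

# Connected-component labelling by iterative label propagation: every
# active voxel starts with a unique label and repeatedly adopts the
# minimum label among its active neighbours until a fixed point.
flood_fill_oracle <- function(binary, connectivity = 26) {
  dims <- dim(binary)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 "26" = offs)
  lab <- array(0, dims)
  act <- which(binary)
  lab[act] <- seq_along(act)
  repeat {
    changed <- FALSE
    for (v in act) {
      vc <- arrayInd(v, dims)
      for (o in seq_len(nrow(offs))) {
        nb <- vc + offs[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        w <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (binary[w] && lab[w] < lab[v]) {
          lab[v] <- lab[w]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sizes <- table(lab[act])
  list(labels = lab, sizes = sort(as.integer(sizes), decreasing = TRUE))
}

# Exact HWE enumeration from multinomial coefficients (normalised sum over
# all heterozygote counts compatible with the allele counts).
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het
  nb <- 2 * n_hom_ref + n_het
  nm <- min(na, nb)
  hets <- seq(nm %% 2, nm, by = 2)
  w <- sapply(hets, function(h) {
    hm <- (nm - h) / 2
    hM <- n - h - hm
    exp(lfactorial(n) - lfactorial(hm) - lfactorial(h) - lfactorial(hM) +
          h * log(2))
  })
  pr <- w / sum(w)
  obs <- pr[hets == n_het]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Greedy windowed LD pruning, literal restatement of the rule.
greedy_prune_oracle <- function(D, chrom, window, step, r2max) {
  maf <- apply(D, 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  keep <- rep(TRUE, ncol(D))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- 1
    repeat {
      win <- idx[s:min(s + window - 1, length(idx))]
      repeat {
        win_alive <- win[keep[win]]
        if (length(win_alive) < 2) break
        R2 <- suppressWarnings(cor(D[, win_alive, drop = FALSE],
                                   use = "pairwise.complete.obs"))^2
        R2[is.na(R2)] <- 0
        diag(R2) <- 0
        if (max(R2) <= r2max) break
        ij <- which(R2 == max(R2), arr.ind = TRUE)[1, ]
        a <- win_alive[ij[1]]; b <- win_alive[ij[2]]
        drop_j <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
        keep[drop_j] <- FALSE
      }
      if (s + window - 1 >= length(idx)) break
      s <- s + step
    }
  }
  which(keep)
}

# Exhaustive assignment: best permutation by total |correlation|.
assignment_brute_force <- function(score) {
  n <- nrow(score)
  perms <- all_perms(seq_len(n))
  best <- NULL
  best_val <- -Inf
  for (p in perms) {
    v <- sum(score[cbind(seq_len(n), p)])
    if (v > best_val) {
      best_val <- v
      best <- p
    }
  }
  list(perm = best, value = best_val)
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Partial correlation via explicit normal-equations residuals.
partial_cor_oracle <- function(x, y, Z) {
  X <- cbind(1, Z)
  bx <- solve(t(X) %*% X, t(X) %*% x)
  by <- solve(t(X) %*% X, t(X) %*% y)
  rx <- x - X %*% bx
  ry <- y - X %*% by
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- length(x) - 2 - ncol(Z)
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Construct (x, y, Z) whose sample partial correlation given Z is exactly r.
make_exact_partial_r <- function(r, n, q, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * q), n, q)
  B <- qr.Q(qr(cbind(1, Z, rnorm(n), rnorm(n))))
  e1 <- B[, q + 2]
  e2 <- B[, q + 3]
  x <- e1
  y <- r * e1 + sqrt(1 - r^2) * e2
  list(x = x, y = y, Z = Z)
}

# Small deterministic genotype matrix for QC tests.
toy_genotypes <- function(n = 40, p = 12, seed = 1, missing = 0) {
  set.seed(seed)
  D <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.5)[rep(seq_len(p), each = n)]),
              n, p)
  if (missing > 0) D[sample(length(D), missing)] <- NA
  snp <- data.frame(id = paste0("s", seq_len(p)),
                    chrom = rep(1L, p), pos = seq_len(p) * 1000L,
                    a1 = "A", a2 = "G")
  genotype_matrix(D, snp, data.frame(id = paste0("i", seq_len(n)),
                                     group = rep(0:1, length.out = n)))
}
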