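# Linked synthetic-data generator.  Emulates the statistical structure the
# fusion analysis assumes: sparse latent components in both modalities,
# cross-modality correlation of subject loadings, a diagnostic-group shift
# on the linked loading columns, Balding-Nichols two-subpopulation allele
# frequencies, exchangeable within-block LD, and exome-chip-like {0,1,2}
# dosages obtained by per-subpopulation quantile discretisation of a latent
# Gaussian field.  Ground truth is returned for recovery testing.

#' Synthetic study configuration
#'
#' Defaults mirror the study conditions the package is exercised under:
#' 198 adolescents of whom 63 are patients, two ancestral subpopulations at
#' FST 0.1, a Table-1-scale cross-modality loading correlation, and
#' desk-scale feature counts.
#'
#' @param n_subjects,n_snps Cohort and marker counts.
#' @param grid_dims 3 positive integers, voxels per axis.
#' @param k_gene,k_brain Latent component counts.
#' @param linked_pairs List of `c(gene_index, brain_index, r)` triples with
#'   `|r| < 1`: loading columns to correlate across modalities.
#' @param group_effect Standardised mean shift of the linked loading
#'   columns in the patient group.
#' @param group_fraction Patient proportion in (0, 1).
#' @param fst Balding-Nichols differentiation in [0, 0.5).
#' @param ld_block_size SNPs per exchangeable LD block.
#' @param ld_within_r Target within-block latent correlation in [0, 1).
#' @param snp_sparsity Fraction of SNPs with nonzero weight per component.
#' @param blob_radius_vox Gaussian radius (sigma, voxels) of spatial blobs.
#' @param noise_sd_gene,noise_sd_brain Additive noise scale, relative to the
#'   root-mean-square amplitude of the noiseless signal matrix.
#' @param maf_range Ancestral minor-allele-frequency spectrum (uniform).
#' @param latent_mode If `TRUE`, skip discretisation/population structure
#'   and return the continuous latent genetic matrix (clean fusion tests).
#' @param seed Master seed; all randomness derives from it.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 198, n_snps = 2000,
                             grid_dims = c(12, 12, 12),
                             k_gene = 4, k_brain = 3,
                             linked_pairs = list(c(1, 1, 0.34)),
                             group_effect = 0.5,
                             group_fraction = 63 / 198,
                             fst = 0.1, ld_block_size = 10,
                             ld_within_r = 0.3, snp_sparsity = 0.05,
                             blob_radius_vox = 1,
                             noise_sd_gene = 0.5, noise_sd_brain = 0.5,
                             maf_range = c(0.05, 0.5),
                             latent_mode = FALSE, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 4, n_snps >= 1, length(grid_dims) == 3,
            all(grid_dims >= 1), k_gene >= 0, k_brain >= 0,
            group_fraction > 0, group_fraction < 1,
            fst >= 0, fst < 0.5, ld_block_size >= 1,
            ld_within_r >= 0, ld_within_r < 1,
            snp_sparsity > 0, snp_sparsity <= 1)
  for (lp in linked_pairs) {
    if (length(lp) != 3) stop_pf("linked pair must be (gene, brain, r)")
    if (lp[1] < 1 || lp[1] > k_gene || lp[2] < 1 || lp[2] > k_brain) {
      stop_pf("linked pair indices out of component range")
    }
    if (abs(lp[3]) >= 1) stop_pf("|link correlation| must be < 1")
  }
  structure(cfg, class = "synthetic_config")
}

#' Smooth sparse spatial sources on a 3D grid
#'
#' Each source is 1-3 smooth positive Gaussian blobs on an otherwise-zero
#' grid, L2-row-normalised.  Blob centres of distinct sources are kept at
#' least 4 sigma apart (2 sigma within a source) so sources are nearly
#' uncorrelated; centres stay at least one sigma inside the grid.
#'
#' @param grid_dims 3 positive integers.
#' @param k Number of sources (0 gives an empty matrix).
#' @param blob_radius_vox Gaussian sigma in voxels (>= 1 recommended).
#' @param seed Integer seed (determinism).
#' @return k x prod(grid_dims) matrix, voxels in x-fastest order.
#' @export
make_spatial_sources <- function(grid_dims, k, blob_radius_vox = 1,
                                 seed = 1) {
  stopifnot(k >= 0, blob_radius_vox >= 1)
  n_vox <- prod(grid_dims)
  if (k == 0) return(matrix(0, 0, n_vox))
  sigma <- blob_radius_vox
  margin <- max(1, ceiling(sigma))
  lo <- rep_len(1 + margin, 3L)
  hi <- grid_dims - margin
  if (any(hi < lo)) stop_pf("grid too small to place blobs of radius %.2g", sigma)

  coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                                  y = seq_len(grid_dims[2]),
                                  z = seq_len(grid_dims[3])))
  lattice <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                   z = lo[3]:hi[3]))
  with_seed(seed, {
    # centres of different sources stay 4 sigma apart (near-zero overlap of
    # the 3-sigma-truncated blobs), 2 sigma within a source; candidates are
    # enumerated and the whole placement restarted if it dead-ends
    valid_candidates <- function(centers, owner, comp) {
      if (nrow(centers) == 0) return(seq_len(nrow(lattice)))
      ok <- rep(TRUE, nrow(lattice))
      for (i in seq_len(nrow(centers))) {
        min_sep <- if (owner[i] == comp) 2 * sigma else 4 * sigma
        d <- sqrt(rowSums(sweep(lattice, 2L, centers[i, ], "-")^2))
        ok <- ok & d >= min_sep
      }
      which(ok)
    }
    centers <- NULL
    for (restart in 1:100) {
      centers <- matrix(numeric(0), 0, 3)
      owner <- integer(0)
      failed <- FALSE
      for (comp in seq_len(k)) {
        cand <- valid_candidates(centers, owner, comp)
        if (length(cand) == 0) {
          failed <- TRUE
          break
        }
        pick <- cand[sample.int(length(cand), 1)]
        centers <- rbind(centers, lattice[pick, ])
        owner <- c(owner, comp)
      }
      if (!failed) break
      centers <- NULL
    }
    if (is.null(centers)) {
      stop_pf("grid too small to place %d disjoint blob sets", k)
    }
    for (comp in seq_len(k)) {          # optional extra blobs, 0-2 each
      extra <- sample(0:2, 1)
      for (b in seq_len(extra)) {
        cand <- valid_candidates(centers, owner, comp)
        if (length(cand) == 0) break
        pick <- cand[sample.int(length(cand), 1)]
        centers <- rbind(centers, lattice[pick, ])
        owner <- c(owner, comp)
      }
    }
    S <- matrix(0, k, n_vox)
    for (i in seq_len(nrow(centers))) {
      d2 <- rowSums(sweep(coords, 2L, centers[i, ], "-")^2)
      sel <- d2 <= (3 * sigma)^2
      S[owner[i], sel] <- S[owner[i], sel] + exp(-0.5 * d2[sel] / sigma^2)
    }
    S / sqrt(rowSums(S^2))
  })
}

#' Sparse heavy-tailed SNP sources
#'
#' Each row carries `round(sparsity * n_snps)` nonzero Laplace-distributed
#' weights, L2-normalised.  Supports of different rows are drawn to minimise
#' overlap (zero overlap whenever `k * m <= n_snps`).
#'
#' @param n_snps Number of SNPs (columns).
#' @param k Number of components (rows).
#' @param sparsity Fraction of nonzero weights per row, in (0, 1].
#' @param seed Integer seed.
#' @return k x n_snps matrix with unit-norm rows.
#' @export
make_snp_sources <- function(n_snps, k, sparsity = 0.05, seed = 1) {
  stopifnot(k >= 0, sparsity > 0, sparsity <= 1)
  if (k == 0) return(matrix(0, 0, n_snps))
  m <- round(sparsity * n_snps)
  if (m < 1) stop_pf("sparsity * n_snps = %.3g < 1: no nonzero weights", sparsity * n_snps)
  with_seed(seed, {
    S <- matrix(0, k, n_snps)
    unused <- seq_len(n_snps)
    for (comp in seq_len(k)) {
      take_new <- min(m, length(unused))
      sup <- if (take_new > 0) sample(unused, take_new) else integer(0)
      if (take_new < m) {
        sup <- c(sup, sample(setdiff(seq_len(n_snps), sup), m - take_new))
      }
      unused <- setdiff(unused, sup)
      w <- sample(c(-1, 1), m, replace = TRUE) * rexp(m)
      S[comp, sup] <- w / sqrt(sum(w^2))
    }
    S
  })
}

#' Generate a linked genotype + volumetric dataset with ground truth
#'
#' Brain data are `brain_loadings %*% brain_sources` plus Gaussian noise,
#' reshaped per subject onto the grid.  Latent genetic data are
#' `gene_loadings %*% gene_sources` plus noise; unless `latent_mode`, the
#' latent field is mixed with a shared per-block Gaussian (exchangeable LD)
#' and discretised to \{0,1,2\} dosages by per-subpopulation quantile
#' cut-points at Hardy-Weinberg genotype proportions for Balding-Nichols
#' subpopulation allele frequencies.  Linked loading columns follow
#' `a2 = r a1 + sqrt(1 - r^2) eps`; the patient group shifts the linked
#' columns by `group_effect` standard deviations.  The covariate table
#' carries age, sex, group, subpopulation and two synthetic clinical scores
#' correlated with the first linked brain loading.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_dataset`: `gene` (subjects x SNPs,
#'   dosages or latent values), `genotypes` (`genotype_matrix`, `NULL` in
#'   latent mode), `brain` (subjects x voxels), `volumes` (4D array),
#'   `mask` (all-`TRUE` grid), `covariates`, `truth` (`synthetic_truth`),
#'   `config`.
#' @export
generate_linked_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  n <- cf$n_subjects
  seeds <- derive_seeds(cf$seed, 8)

  gene_sources <- make_snp_sources(cf$n_snps, cf$k_gene, cf$snp_sparsity,
                                   seeds[1])
  brain_sources <- make_spatial_sources(cf$grid_dims, cf$k_brain,
                                        cf$blob_radius_vox, seeds[2])

  link_mat <- do.call(rbind, cf$linked_pairs)
  A_g <- with_seed(seeds[3], matrix(rnorm(n * cf$k_gene), n, cf$k_gene))
  A_b <- with_seed(seeds[4], {
    A <- matrix(rnorm(n * cf$k_brain), n, cf$k_brain)
    if (!is.null(link_mat)) {
      for (row in seq_len(nrow(link_mat))) {
        gi <- link_mat[row, 1]; bj <- link_mat[row, 2]; r <- link_mat[row, 3]
        A[, bj] <- r * A_g[, gi] + sqrt(1 - r^2) * rnorm(n)
      }
    }
    A
  })

  n_pat <- round(cf$group_fraction * n)
  group <- integer(n)
  group[with_seed(seeds[5], sample.int(n, n_pat))] <- 1L
  if (!is.null(link_mat)) {
    for (row in seq_len(nrow(link_mat))) {
      A_g[group == 1L, link_mat[row, 1]] <-
        A_g[group == 1L, link_mat[row, 1]] + cf$group_effect
      A_b[group == 1L, link_mat[row, 2]] <-
        A_b[group == 1L, link_mat[row, 2]] + cf$group_effect
    }
  }
  subpop <- rep_len(c(0L, 1L), n)
  subpop <- with_seed(seeds[5] + 1L, sample(subpop))

  sig_b <- A_b %*% brain_sources
  rms_b <- sqrt(mean(sig_b^2))
  if (rms_b == 0) rms_b <- 1          # no signal: noise on unit scale
  Y <- sig_b + cf$noise_sd_brain * rms_b *
    with_seed(seeds[6], matrix(rnorm(length(sig_b)), nrow(sig_b)))

  sig_g <- A_g %*% gene_sources
  rms_g <- sqrt(mean(sig_g^2))
  if (rms_g == 0) rms_g <- 1
  L <- sig_g + cf$noise_sd_gene * rms_g *
    with_seed(seeds[7], matrix(rnorm(length(sig_g)), nrow(sig_g)))

  snp_records <- synth_snp_records(cf$n_snps)
  geno <- NULL
  gene_out <- L
  target_maf <- rep(NA_real_, cf$n_snps)
  if (!cf$latent_mode) {
    disc <- discretize_genotypes(L, subpop, cf, seeds[8])
    gene_out <- disc$dosages
    target_maf <- disc$target_maf
    sample_records <- data.frame(id = sprintf("S%04d", seq_len(n)))
    geno <- genotype_matrix(disc$dosages, snp_records,
                            cbind(sample_records,
                                  group = group, subpop = subpop))
  }

  covars <- with_seed(seeds[5] + 2L, {
    clin_src <- if (!is.null(link_mat)) A_b[, link_mat[1, 2]] else A_b[, 1]
    zz <- as.numeric(scale(clin_src))
    data.frame(
      id = sprintf("S%04d", seq_len(n)),
      age = round(runif(n, 12, 18), 1),
      sex = rbinom(n, 1, 0.5),
      group = group,
      subpop = subpop,
      attention_score = round(50 + 10 * (0.4 * zz + sqrt(1 - 0.16) * rnorm(n)), 1),
      omission_score = round(50 + 10 * (0.4 * zz + sqrt(1 - 0.16) * rnorm(n)), 1))
  })

  realized <- if (is.null(link_mat)) numeric(0) else
    vapply(seq_len(nrow(link_mat)), function(rw) {
      cor(A_g[, link_mat[rw, 1]], A_b[, link_mat[rw, 2]])
    }, numeric(1))

  truth <- structure(list(
    gene_sources = gene_sources, brain_sources = brain_sources,
    gene_loadings = A_g, brain_loadings = A_b,
    group_labels = group, subpop_labels = subpop,
    linked_pairs = cf$linked_pairs,
    realized_link_correlations = realized,
    target_maf = target_maf), class = "synthetic_truth")

  volumes <- array(t(Y), c(cf$grid_dims, n))
  structure(list(gene = gene_out, genotypes = geno, brain = Y,
                 volumes = volumes,
                 mask = array(TRUE, cf$grid_dims),
                 covariates = covars, truth = truth, config = cf),
            class = "synthetic_dataset")
}

synth_snp_records <- function(n_snps) {
  half <- ceiling(n_snps / 2)
  chrom <- rep(c(1L, 2L), c(half, n_snps - half))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom),
                       function(ix) 10000L * seq_along(ix)), use.names = FALSE)
  data.frame(id = sprintf("rs%05d", seq_len(n_snps)), chrom = chrom,
             pos = pos, a1 = "A", a2 = "G")
}

# Quantile discretisation of a latent Gaussian field to {0,1,2} dosages at
# Balding-Nichols per-subpopulation Hardy-Weinberg proportions.
discretize_genotypes <- function(L, subpop, cf, seed) {
  n <- nrow(L); p <- ncol(L)
  Lstd <- scale(L)
  Lstd[, attr(Lstd, "scaled:scale") == 0] <- 0
  with_seed(seed, {
    p0 <- runif(p, cf$maf_range[1], cf$maf_range[2])
    freqs <- sapply(0:1, function(s) {
      if (cf$fst == 0) p0 else {
        shape <- (1 - cf$fst) / cf$fst
        rbeta(p, p0 * shape, (1 - p0) * shape)
      }
    })                                  # p x 2 matrix of subpop alt freqs
    # confine drifted frequencies to the declared spectrum so the requested
    # markers stay polymorphic at realistic sample sizes
    freqs <- pmin(pmax(freqs, cf$maf_range[1] / 2), 1 - cf$maf_range[1] / 2)
    blocks <- ceiling(seq_len(p) / cf$ld_block_size)
    U <- matrix(rnorm(n * max(blocks)), n)
    E_blk <- U[, blocks, drop = FALSE]
    z <- sqrt(1 - cf$ld_within_r) * Lstd + sqrt(cf$ld_within_r) * E_blk

    D <- matrix(0L, n, p)
    for (s in 0:1) {
      rows <- which(subpop == s)
      ns <- length(rows)
      for (j in seq_len(p)) {
        pf <- freqs[j, s + 1]
        n2 <- round(ns * pf^2)
        n0 <- round(ns * (1 - pf)^2)
        if (n0 + n2 > ns) n0 <- ns - n2
        rk <- rank(z[rows, j], ties.method = "first")
        g <- integer(ns)
        g[rk > ns - n2] <- 2L
        g[rk > n0 & rk <= ns - n2] <- 1L
        D[rows, j] <- g
      }
    }
    mono <- which(apply(D, 2L, function(x) length(unique(x))) == 1L)
    if (length(mono) > 0) {
      stop_pf("monomorphic dosage requested at SNP index %d (target MAF too extreme for the sample size)", mono[1])
    }
    n0s <- sum(subpop == 0); n1s <- sum(subpop == 1)
    mix <- (n0s * freqs[, 1] + n1s * freqs[, 2]) / n
    list(dosages = D, target_maf = pmin(mix, 1 - mix),
         subpop_freqs = freqs)
  })
}

#' Hudson estimator of FST between two subpopulations
#'
#' Ratio-of-averages Hudson FST over SNPs from dosage data:
#' per-SNP numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`, averaged before taking the ratio.
#'
#' @param dosages subjects x SNPs matrix in \{0,1,2\}.
#' @param subpop Binary subpopulation labels.
#' @return Scalar FST estimate.
#' @export
hudson_fst <- function(dosages, subpop) {
  s0 <- subpop == unique(subpop)[1]
  n1 <- sum(s0); n2 <- sum(!s0)
  p1 <- colMeans(dosages[s0, , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(dosages[!s0, , drop = FALSE], na.rm = TRUE) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

#' Synthetic gene model over the simulated SNP map
#'
#' Tiles each chromosome's SNPs into consecutive runs of varying size
#' (geometric-ish mix of small and large genes) and emits 1-based inclusive
#' gene intervals covering them, leaving every `gap_every`-th SNP
#' intergenic so unassigned SNPs exist.
#'
#' @param snp_records data.frame with `id`, `chrom`, `pos`.
#' @param min_snps,max_snps Gene size range in SNPs.
#' @param gap_every Leave a gap after every this-many genes.
#' @param seed Integer seed.
#' @return data.frame(symbol, chrom, start, end), class `gene_model`.
#' @export
synth_gene_model <- function(snp_records, min_snps = 1, max_snps = 20,
                             gap_every = 5, seed = 1) {
  with_seed(seed, {
    out <- list()
    g <- 0L
    for (ch in unique(snp_records$chrom)) {
      pos <- snp_records$pos[snp_records$chrom == ch]
      i <- 1L
      while (i <= length(pos)) {
        size <- sample(min_snps:max_snps, 1)
        j <- min(i + size - 1L, length(pos))
        g <- g + 1L
        out[[g]] <- data.frame(symbol = sprintf("GENE%04d", g), chrom = ch,
                               start = pos[i] - 100L, end = pos[j] + 100L)
        i <- j + 1L
        if (g %% gap_every == 0L) i <- i + 1L  # intergenic SNP
      }
    }
    res <- do.call(rbind, out)
    class(res) <- c("gene_model", class(res))
    res
  })
}

#' Synthetic pathway gene sets
#'
#' Random gene sets over the supplied symbols, one enriched pathway
#' optionally seeded from `enriched_genes`.
#'
#' @param gene_symbols Background gene symbols.
#' @param n_pathways Number of pathways.
#' @param size_range Pathway size range.
#' @param enriched_genes Optional genes forced into the first pathway.
#' @param seed Integer seed.
#' @return Named list of character vectors (GMT-style).
#' @export
synth_pathways <- function(gene_symbols, n_pathways = 20,
                           size_range = c(5, 40), enriched_genes = NULL,
                           seed = 1) {
  with_seed(seed, {
    sets <- lapply(seq_len(n_pathways), function(i) {
      size <- sample(size_range[1]:size_range[2], 1)
      sample(gene_symbols, min(size, length(gene_symbols)))
    })
    names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_pathways))
    if (!is.null(enriched_genes)) {
      sets[[1]] <- unique(c(enriched_genes,
                            sets[[1]][seq_len(min(5, length(sets[[1]])))]))
    }
    sets
  })
}
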