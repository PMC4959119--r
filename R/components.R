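# Fusion core, part 2: component containers, spatial-map thresholding, and
# component matching across runs.

# Build a per-modality component model from an unmixing matrix and the
# whitening bundle.  Sources are W %*% Z (K x features); loadings are the
# dewhitened mixing columns (subjects x K).  Components are reordered by
# descending explained variance and sign-fixed so each source's largest
# |element| is positive.
component_model <- function(X, W, wh, modality = "unknown") {
  K <- nrow(W)
  S <- W %*% wh$whitened                    # K x features
  A <- wh$dewhitening %*% solve(W)          # subjects x K
  tot <- sum(sweep(X, 2L, wh$col_means, "-")^2)
  ev <- vapply(seq_len(K), function(k) {
    sum(outer(A[, k], S[k, ])^2) / max(tot, 1e-300)
  }, numeric(1))
  ord <- order(ev, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  ev <- ev[ord]
  for (k in seq_len(K)) {
    sgn <- sign(S[k, which.max(abs(S[k, ]))])
    if (sgn < 0) {
      S[k, ] <- -S[k, ]
      A[, k] <- -A[, k]
    }
  }
  structure(list(loadings = A, sources = S, modality = modality,
                 explained_variance = ev),
            class = "component_model")
}

#' Threshold a component map into suprathreshold clusters
#'
#' Z-scores a source row over the in-mask voxels, keeps voxels with
#' `|z| > z_thresh`, groups them into connected components on the 3D grid,
#' and returns clusters larger than `min_cluster` voxels sorted by peak
#' `|z|` (the dominant-region rule `|z| > 1.5`, cluster size `k > 50`).
#'
#' @param source_row Numeric vector over in-mask voxels.
#' @param mask Logical 3D array defining the grid support.
#' @param z_thresh Absolute z threshold.
#' @param min_cluster Minimum cluster size (strictly greater than).
#' @param connectivity 6, 18 or 26 (face / edge / corner neighbours).
#' @return data.frame of class `cluster_table`: columns `size`, `peak_z`
#'   (signed z at the peak |z| voxel), `peak_x`, `peak_y`, `peak_z_coord`,
#'   and a list-column `voxels` of linear grid indices.
#' @export
threshold_component_map <- function(source_row, mask, z_thresh = 1.5,
                                    min_cluster = 50, connectivity = 26) {
  mask <- array(as.logical(mask), dim(mask))
  if (length(source_row) != sum(mask)) {
    stop_pf("source row length %d != mask support %d",
            length(source_row), sum(mask))
  }
  s <- sd(source_row)
  if (s == 0) stop_pf("zero-variance source cannot be z-scored")
  z <- (source_row - mean(source_row)) / s
  zvol <- unflatten_map(z, mask)
  supra <- abs(zvol) > z_thresh & mask
  lab <- label_components(supra, connectivity)
  tab <- empty_cluster_table()
  if (lab$n > 0) {
    dims <- dim(mask)
    for (cl in seq_len(lab$n)) {
      vox <- which(lab$labels == cl)
      if (length(vox) <= min_cluster) next
      zv <- zvol[vox]
      peak <- vox[which.max(abs(zv))]
      pc <- arrayInd(peak, dims)
      tab <- rbind(tab, data.frame(
        size = length(vox), peak_z = zvol[peak],
        peak_x = pc[1], peak_y = pc[2], peak_z_coord = pc[3],
        voxels = I(list(vox))))
    }
  }
  tab <- tab[order(-abs(tab$peak_z)), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("cluster_table", class(tab))
  tab
}

empty_cluster_table <- function() {
  data.frame(size = integer(0), peak_z = numeric(0), peak_x = integer(0),
             peak_y = integer(0), peak_z_coord = integer(0),
             voxels = I(list()))
}

neighbour_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(offs)) == 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)),
                 stop_pf("connectivity must be 6, 18 or 26"))
  offs[keep, , drop = FALSE]
}

# Breadth-first connected-component labelling of a logical 3D array.
label_components <- function(binary, connectivity = 26) {
  dims <- dim(binary)
  offs <- neighbour_offsets(connectivity)
  labels <- array(0L, dims)
  active <- which(binary)
  n_lab <- 0L
  for (start in active) {
    if (labels[start] != 0L) next
    n_lab <- n_lab + 1L
    queue <- start
    labels[start] <- n_lab
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      vc <- arrayInd(v, dims)
      nb <- sweep(offs, 2L, as.integer(vc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      lin <- lin[binary[lin] & labels[lin] == 0L]
      if (length(lin) > 0) {
        labels[lin] <- n_lab
        queue <- c(queue, lin)
      }
    }
  }
  list(labels = labels, n = n_lab)
}

#' Match two component sets by maximal absolute correlation
#'
#' Finds the one-to-one assignment between the rows of `sources_a` and
#' `sources_b` maximising the total absolute Pearson correlation (optimal
#' assignment via the Hungarian algorithm), with signs chosen so matched
#' correlations are positive.  When the sets have different sizes the
#' smaller side is fully matched and unmatched components are reported.
#'
#' @param sources_a,sources_b K_a x features and K_b x features matrices.
#' @return list(permutation = for each row of `sources_a` the matched row of
#'   `sources_b` (NA if unmatched), signs, correlations = signed matched
#'   correlations, unmatched_b = rows of `sources_b` left unmatched).
#' @export
match_components <- function(sources_a, sources_b) {
  A <- as.matrix(sources_a); B <- as.matrix(sources_b)
  if (ncol(A) != ncol(B)) stop_pf("feature dimensions differ")
  Ka <- nrow(A); Kb <- nrow(B)
  if (Ka == 0 || Kb == 0) {
    return(list(permutation = rep(NA_integer_, Ka), signs = numeric(0),
                correlations = numeric(0), unmatched_b = seq_len(Kb)))
  }
  C <- suppressWarnings(cor(t(A), t(B)))
  C[is.na(C)] <- 0
  assign <- hungarian_max(abs(C))
  perm <- rep(NA_integer_, Ka)
  perm[assign[, 1]] <- assign[, 2]
  signs <- sign(C[assign])
  signs[signs == 0] <- 1
  corrs <- C[assign] * signs
  list(permutation = perm,
       signs = setNames(signs, assign[, 1]),
       correlations = setNames(corrs, assign[, 1]),
       matched_abs = setNames(abs(C[assign]), assign[, 1]),
       unmatched_b = setdiff(seq_len(Kb), assign[, 2]))
}

# Optimal assignment maximising sum of scores (rows to columns, rectangular
# allowed; min(nrow, ncol) pairs returned).  Munkres algorithm on the padded
# square cost matrix.
hungarian_max <- function(score) {
  n <- max(dim(score))
  cost <- matrix(max(score), n, n)   # padding cost: neutral
  cost[seq_len(nrow(score)), seq_len(ncol(score))] <- -score
  cost <- cost - min(cost)
  assign <- munkres(cost)
  keep <- assign[, 1] <= nrow(score) & assign[, 2] <= ncol(score)
  assign <- assign[keep, , drop = FALSE]
  assign[order(assign[, 1]), , drop = FALSE]
}

# Classical Munkres (Hungarian) algorithm for square cost minimisation.
munkres <- function(cost) {
  n <- nrow(cost)
  C <- sweep(cost, 1L, apply(cost, 1L, min), "-")
  C <- sweep(C, 2L, apply(C, 2L, min), "-")
  starred <- matrix(FALSE, n, n)
  primed <- matrix(FALSE, n, n)
  row_cov <- rep(FALSE, n)
  col_cov <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (C[i, j] == 0 && !row_cov[i] && !col_cov[j]) {
        starred[i, j] <- TRUE
        row_cov[i] <- TRUE
        col_cov[j] <- TRUE
      }
    }
  }
  row_cov[] <- FALSE; col_cov[] <- FALSE
  repeat {
    col_cov <- apply(starred, 2L, any)
    if (sum(col_cov) == n) break
    repeat {
      z <- find_uncovered_zero(C, row_cov, col_cov)
      while (is.null(z)) {
        # augment: subtract min uncovered from uncovered, add to doubly covered
        m <- min(C[!row_cov, !col_cov, drop = FALSE])
        C[row_cov, ] <- C[row_cov, , drop = FALSE] + m
        C[, !col_cov] <- C[, !col_cov, drop = FALSE] - m
        z <- find_uncovered_zero(C, row_cov, col_cov)
      }
      primed[z[1], z[2]] <- TRUE
      star_col <- which(starred[z[1], ])
      if (length(star_col) == 0) {
        # augmenting path of alternating primes and stars
        path <- matrix(z, 1, 2)
        repeat {
          r <- which(starred[, path[nrow(path), 2]])
          if (length(r) == 0) break
          path <- rbind(path, c(r, path[nrow(path), 2]))
          cc <- which(primed[r, ])[1]
          path <- rbind(path, c(r, cc))
        }
        for (k in seq_len(nrow(path))) {
          i <- path[k, 1]; j <- path[k, 2]
          starred[i, j] <- !starred[i, j]
        }
        primed[] <- FALSE
        row_cov[] <- FALSE
        col_cov[] <- FALSE
        break
      } else {
        row_cov[z[1]] <- TRUE
        col_cov[star_col] <- FALSE
      }
    }
  }
  which(starred, arr.ind = TRUE)
}

find_uncovered_zero <- function(C, row_cov, col_cov) {
  rows <- which(!row_cov)
  for (i in rows) {
    j <- which(C[i, ] == 0 & !col_cov)
    if (length(j) > 0) return(c(i, j[1]))
  }
  NULL
}
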