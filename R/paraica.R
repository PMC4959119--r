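# Parallel ICA: alternating per-modality Infomax epochs plus a coupling step
# that increases the squared correlation between the subject loading columns
# of the currently best-linked component pair.
#
# The loadings are an analytic function of the unmixing matrix: with
# whitened data Z = Wh (X - mu) and dewhitening M (subjects x K), the
# loading matrix is A = M W^-1, so column i of A is M %*% Winv[, i].  The
# coupling step performs gradient ascent of corr^2(a_gene_i, a_brain_j)
# directly on the relevant columns of the two inverse unmixing matrices;
# with lambda = 0 the step is skipped entirely and the two Infomax update
# sequences are bit-identical to independent runs.

infomax_entropy <- function(W, Z) {
  U <- W %*% Z
  G <- 1 / (1 + exp(-U))
  determinant(W, logarithm = TRUE)$modulus[1] +
    mean(colSums(log(pmax(G * (1 - G), 1e-300))))
}

# One accepted-or-rejected Infomax epoch: the epoch is rolled back (and the
# learning rate halved) if it decreased the entropy objective, so the
# objective is non-decreasing over accepted epochs.
infomax_epoch_accepted <- function(st, epoch) {
  snap <- st
  st <- infomax_epoch(st, epoch)
  if (st$diverged) return(st)
  ent <- infomax_entropy(st$W, st$Z)
  prev <- snap$entropy
  if (!is.null(prev) && ent < prev - 1e-9 * abs(prev)) {
    st <- snap
    st$lr <- snap$lr * 0.5
    st$epoch <- epoch
    st$last_change <- Inf
    st$accepted <- FALSE
    st$rejections <- (snap$rejections %||% 0L) + 1L
  } else {
    st$entropy <- ent
    st$accepted <- TRUE
    st$rejections <- snap$rejections %||% 0L
  }
  st
}

# Gradient of corr(u, v) with respect to u (centering included).
corr_grad_u <- function(u, v) {
  uc <- u - mean(u); vc <- v - mean(v)
  nu <- sqrt(sum(uc^2)); nv <- sqrt(sum(vc^2))
  r <- sum(uc * vc) / (nu * nv)
  g <- vc / (nu * nv) - r * uc / nu^2
  list(r = r, grad = g - mean(g))
}

# One coupling step on the (i, j) loading pair.  Returns updated inverse
# unmixing matrices; backtracks the step size until corr^2 increases (up to
# 6 halvings, else leaves the matrices untouched).
coupling_step <- function(Winv_g, Winv_b, Mg, Mb, i, j, eta_rel) {
  cg <- Winv_g[, i]; cb <- Winv_b[, j]
  u <- drop(Mg %*% cg); v <- drop(Mb %*% cb)
  gu <- corr_grad_u(u, v)
  gv <- corr_grad_u(v, u)
  r0 <- gu$r
  grad_cg <- drop(crossprod(Mg, 2 * r0 * gu$grad))
  grad_cb <- drop(crossprod(Mb, 2 * r0 * gv$grad))
  ng <- sqrt(sum(grad_cg^2)); nb <- sqrt(sum(grad_cb^2))
  if (ng == 0 && nb == 0) return(list(Winv_g = Winv_g, Winv_b = Winv_b,
                                      r = r0, moved = FALSE))
  eta <- eta_rel
  for (try in 1:7) {
    cg_new <- if (ng > 0) cg + eta * sqrt(sum(cg^2)) * grad_cg / ng else cg
    cb_new <- if (nb > 0) cb + eta * sqrt(sum(cb^2)) * grad_cb / nb else cb
    r_new <- suppressWarnings(
      cor(drop(Mg %*% cg_new), drop(Mb %*% cb_new)))
    if (is.finite(r_new) && r_new^2 > r0^2) {
      Winv_g[, i] <- cg_new
      Winv_b[, j] <- cb_new
      return(list(Winv_g = Winv_g, Winv_b = Winv_b, r = r_new, moved = TRUE))
    }
    eta <- eta / 2
  }
  list(Winv_g = Winv_g, Winv_b = Winv_b, r = r0, moved = FALSE)
}

#' Parallel ICA of a genetic and a brain phenotype matrix
#'
#' Runs natural-gradient Infomax ICA on each modality in parallel
#' (alternating epochs) and, between epochs, applies a coupling update that
#' increases the squared correlation of the subject loading columns of the
#' maximally correlated cross-modality component pair, provided its absolute
#' correlation is at least `tau_link` and below `r_cap` (the cap prevents
#' collapse of within-modality independence).  With `lambda = 0` the result
#' is bit-identical to two independent [run_infomax()] runs under the same
#' derived seeds.
#'
#' @param X_gene,X_brain subjects x features matrices, identical row order.
#' @param K_gene,K_brain Component counts per modality (e.g. from
#'   [estimate_order_mdl()]).
#' @param lambda Coupling strength; the relative coupling step per epoch is
#'   `lambda` times the mean relative Infomax weight change, so the coupling
#'   gradient stays an order of magnitude below the Infomax gradient at the
#'   default `lambda = 0.1` x 10 = 1 scale.  `0` disables coupling.
#' @param tau_link Minimum |loading correlation| for a pair to be coupled.
#' @param r_cap Pairs with |r| above this are not pushed further.
#' @param n_couple Number of top pairs coupled per epoch.
#' @param max_epochs,batch_size,tol,lr Infomax controls (see
#'   [run_infomax()]).
#' @param seed Master seed; per-modality seeds are derived from it.
#' @return Object of class `para_ica_result`: `gene_model`, `brain_model`
#'   ([component_model] lists), `linked_pairs` (data.frame gene, brain, r for
#'   all pairs with |r| >= tau_link in final ordering), `objective_trace`,
#'   `converged`, `config`, plus raw unmixing matrices `gene_W`, `brain_W`.
#' @export
run_para_ica <- function(X_gene, X_brain, K_gene, K_brain,
                         lambda = 1, tau_link = 0.25, r_cap = 0.95,
                         n_couple = 1, max_epochs = 500, batch_size = 128,
                         tol = 1e-5, lr = NULL, seed = 1) {
  X_gene <- as.matrix(X_gene); X_brain <- as.matrix(X_brain)
  if (nrow(X_gene) != nrow(X_brain)) {
    stop_pf("modalities have different subject counts (%d vs %d)",
            nrow(X_gene), nrow(X_brain))
  }
  seeds <- derive_seeds(seed, 2)
  wh_g <- pca_whiten(X_gene, K_gene)
  wh_b <- pca_whiten(X_brain, K_brain)
  st_g <- infomax_init(wh_g$whitened, max_epochs, lr, batch_size, seeds[1])
  st_b <- infomax_init(wh_b$whitened, max_epochs, lr, batch_size, seeds[2])
  conv_g <- FALSE; conv_b <- FALSE
  trace <- vector("list", max_epochs)

  for (epoch in seq_len(max_epochs)) {
    ent_g_pre <- st_g$entropy %||% NA_real_
    ent_b_pre <- st_b$entropy %||% NA_real_
    if (!conv_g) {
      st_g <- infomax_epoch_accepted(st_g, epoch)
      if (st_g$diverged) stop_pf("gene-modality Infomax diverged at epoch %d; rerun with a smaller learning rate", epoch)
      if (isTRUE(st_g$accepted) && st_g$last_change < tol) conv_g <- TRUE
    }
    if (!conv_b) {
      st_b <- infomax_epoch_accepted(st_b, epoch)
      if (st_b$diverged) stop_pf("brain-modality Infomax diverged at epoch %d; rerun with a smaller learning rate", epoch)
      if (isTRUE(st_b$accepted) && st_b$last_change < tol) conv_b <- TRUE
    }

    ent_g_mid <- st_g$entropy %||% NA_real_   # post-Infomax, pre-coupling
    ent_b_mid <- st_b$entropy %||% NA_real_
    coupling_term <- 0
    pair_txt <- NA_character_
    if (lambda > 0) {
      Winv_g <- solve(st_g$W); Winv_b <- solve(st_b$W)
      A_g <- wh_g$dewhitening %*% Winv_g
      A_b <- wh_b$dewhitening %*% Winv_b
      R <- suppressWarnings(cor(A_g, A_b))
      R[is.na(R)] <- 0
      pairs <- top_pairs(R, n_couple, tau_link, r_cap)
      if (nrow(pairs) > 0) {
        rel <- mean(c(if (conv_g) 0 else min(st_g$last_change, 0.1),
                      if (conv_b) 0 else min(st_b$last_change, 0.1)))
        eta_rel <- lambda * max(rel, 1e-4)
        moved <- FALSE
        for (k in seq_len(nrow(pairs))) {
          cs <- coupling_step(Winv_g, Winv_b, wh_g$dewhitening,
                              wh_b$dewhitening, pairs$gene[k],
                              pairs$brain[k], eta_rel)
          Winv_g <- cs$Winv_g; Winv_b <- cs$Winv_b
          coupling_term <- coupling_term + cs$r^2
          moved <- moved || cs$moved
        }
        if (moved) {
          st_g$W <- solve(Winv_g)
          st_b$W <- solve(Winv_b)
          st_g$entropy <- infomax_entropy(st_g$W, st_g$Z)
          st_b$entropy <- infomax_entropy(st_b$W, st_b$Z)
          # coupling perturbs the weights, so convergence must be re-earned
          conv_g <- conv_g && !moved
          conv_b <- conv_b && !moved
        }
        pair_txt <- paste(sprintf("g%d-b%d", pairs$gene, pairs$brain),
                          collapse = ",")
      }
    }
    trace[[epoch]] <- data.frame(
      epoch = epoch,
      entropy_gene_pre = ent_g_pre, entropy_gene = ent_g_mid,
      entropy_brain_pre = ent_b_pre, entropy_brain = ent_b_mid,
      entropy_gene_post = st_g$entropy %||% NA_real_,
      entropy_brain_post = st_b$entropy %||% NA_real_,
      coupling = coupling_term,
      accepted_gene = isTRUE(st_g$accepted),
      accepted_brain = isTRUE(st_b$accepted),
      coupled_pairs = pair_txt)
    if (conv_g && conv_b) break
  }

  gene_model <- component_model(X_gene, st_g$W, wh_g, "gene")
  brain_model <- component_model(X_brain, st_b$W, wh_b, "brain")
  R_final <- suppressWarnings(cor(gene_model$loadings, brain_model$loadings))
  R_final[is.na(R_final)] <- 0
  lp <- which(abs(R_final) >= tau_link, arr.ind = TRUE)
  linked <- data.frame(gene = lp[, 1], brain = lp[, 2],
                       r = R_final[lp])
  linked <- linked[order(-abs(linked$r)), , drop = FALSE]
  rownames(linked) <- NULL

  structure(list(
    gene_model = gene_model, brain_model = brain_model,
    linked_pairs = linked,
    objective_trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
    converged = conv_g && conv_b,
    gene_W = st_g$W, brain_W = st_b$W,
    whiten_gene = wh_g, whiten_brain = wh_b,
    config = list(K_gene = K_gene, K_brain = K_brain, lambda = lambda,
                  tau_link = tau_link, r_cap = r_cap, n_couple = n_couple,
                  max_epochs = max_epochs, batch_size = batch_size,
                  tol = tol, lr = lr, seed = seed, derived_seeds = seeds)),
    class = "para_ica_result")
}

# Greedy selection of up to m disjoint pairs by descending |r|, restricted
# to tau_link <= |r| <= r_cap.
top_pairs <- function(R, m, tau_link, r_cap) {
  out <- data.frame(gene = integer(0), brain = integer(0), r = numeric(0))
  A <- abs(R)
  A[A < tau_link | A > r_cap] <- NA
  while (nrow(out) < m && any(is.finite(A))) {
    ij <- which(A == max(A, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(gene = ij[1], brain = ij[2],
                                 r = R[ij[1], ij[2]]))
    A[ij[1], ] <- NA
    A[, ij[2]] <- NA
  }
  out
}
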