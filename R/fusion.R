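# Fusion core, part 1: model-order selection and per-modality Infomax ICA.
#
# Orientation convention (used throughout): the data matrix X is
# subjects x features; X ~ A S with loadings A (subjects x K) and sources
# S (K x features).  ICA treats the feature columns as i.i.d. observations
# of a K-dimensional random vector, so sources live over features and the
# per-subject loading coefficients are the quantities tested downstream.

#' Minimum-description-length model order selection
#'
#' Wax-Kailath MDL over the eigenvalues of the sample covariance:
#' `MDL(k) = -n (p-k) log(GM_k / AM_k) + k (2p - k) log(n) / 2`,
#' where `GM_k`/`AM_k` are the geometric/arithmetic means of the trailing
#' `p - k` eigenvalues, `n` is the number of observations (subjects) and
#' `p = min(subjects, features)`.  Returns the argmin over `k` in
#' `[0, p - 1]`.
#'
#' @param X subjects x features numeric matrix.
#' @return list(K = selected order, mdl = the criterion for every k,
#'   eigenvalues = the p sample eigenvalues used).
#' @export
estimate_order_mdl <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop_pf("need at least 2 subjects")
  p <- min(dim(X))
  Xc <- center_cols(X)
  # eigenvalues of the sample covariance; via the smaller Gram matrix
  ev <- if (ncol(X) <= n) {
    eigen(crossprod(Xc) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- pmax(ev[seq_len(p)], 0)
  # centring (and features >= subjects) produces numerically null
  # eigenvalues; the criterion is evaluated on the meaningful spectrum
  p_eff <- sum(ev > max(ev) * 1e-10)
  if (p_eff < 2) stop_pf("fewer than 2 distinct eigenvalues")
  ev_use <- ev[seq_len(p_eff)]
  ks <- 0:(p_eff - 1)
  mdl <- vapply(ks, function(k) {
    tail_ev <- ev_use[(k + 1):p_eff]
    gm <- mean(log(tail_ev))
    am <- log(mean(tail_ev))
    -n * (p_eff - k) * (gm - am) + 0.5 * k * (2 * p_eff - k) * log(n)
  }, numeric(1))
  list(K = ks[which.min(mdl)], mdl = setNames(mdl, ks), eigenvalues = ev)
}

#' PCA whitening to K dimensions
#'
#' Centres the feature columns and projects the subject dimension onto the
#' leading K principal axes, scaled so the whitened rows have identity
#' covariance across features.  The dewhitening transform maps whitened
#' rows back to subject space, so `dewhitening %*% whitened` is the rank-K
#' approximation of the centred data.
#'
#' @param X subjects x features matrix.
#' @param K Target dimension, at most `rank(X)`.
#' @return list(whitened = K x features, whitening = K x subjects,
#'   dewhitening = subjects x K, col_means = feature means removed).
#' @export
pca_whiten <- function(X, K) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc, nu = min(dim(Xc)), nv = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (K > rank) stop_pf("K = %d exceeds rank(X) = %d", K, rank)
  p <- ncol(X)
  d <- sv$d[seq_len(K)]
  U <- sv$u[, seq_len(K), drop = FALSE]
  # rows of Z have unit variance over the p feature-samples
  scale_fac <- d / sqrt(p)
  whitening <- diag(1 / scale_fac, K) %*% t(U)
  Z <- whitening %*% Xc
  dewhitening <- U %*% diag(scale_fac, K)
  list(whitened = Z, whitening = whitening, dewhitening = dewhitening,
       col_means = mu)
}

#' Natural-gradient Infomax ICA
#'
#' Infomax with the logistic nonlinearity `g(u) = 1 / (1 + exp(-u))` and the
#' natural-gradient update `dW = eta (I + (1 - 2 g(U)) U') W` over
#' randomised mini-batches.  The learning rate is annealed (x 0.9) whenever
#' the angle between successive weight changes exceeds 60 degrees; iteration
#' stops when the relative Frobenius change of `W` over an epoch drops below
#' `tol` or `max_epochs` is reached.
#'
#' @param X_whitened K x n_samples whitened data (rows uncorrelated, unit
#'   variance).
#' @param max_epochs Maximum passes over the data.
#' @param lr Initial learning rate.
#' @param batch_size Mini-batch size (samples per update).
#' @param tol Relative Frobenius-change stopping tolerance.
#' @param seed Integer seed controlling batch shuffling (determinism).
#' @return list(W = K x K unmixing matrix, converged, epochs,
#'   epoch_changes, lr_final).
#' @export
run_infomax <- function(X_whitened, max_epochs = 500, lr = NULL,
                        batch_size = 128, tol = 1e-5, seed = 1) {
  st <- infomax_init(X_whitened, max_epochs, lr, batch_size, seed)
  for (epoch in seq_len(max_epochs)) {
    st <- infomax_epoch_accepted(st, epoch)
    if (st$diverged) {
      stop_pf("Infomax diverged (non-finite weights) at epoch %d; rerun with a smaller learning rate", epoch)
    }
    if (isTRUE(st$accepted) && st$last_change < tol) {
      st$converged <- TRUE
      break
    }
  }
  list(W = st$W, converged = st$converged, epochs = st$epoch,
       epoch_changes = st$changes, lr_final = st$lr,
       entropy = st$entropy, rejections = st$rejections %||% 0L)
}

# Internal: shared state constructor so run_para_ica can interleave epochs
# of the exact same update sequence (the lambda = 0 decoupling contract).
infomax_init <- function(Z, max_epochs, lr, batch_size, seed) {
  K <- nrow(Z)
  p <- ncol(Z)
  batch_size <- min(batch_size, p)
  if (is.null(lr)) lr <- 0.01 / log(K + 2)
  # all batch permutations precomputed from the seed: epochs consume no RNG
  perms <- with_seed(seed, lapply(seq_len(max_epochs), function(i) sample.int(p)))
  list(Z = Z, W = diag(K), K = K, p = p, lr = lr, batch_size = batch_size,
       perms = perms, prev_delta = NULL, changes = numeric(0),
       last_change = Inf, epoch = 0L, converged = FALSE, diverged = FALSE)
}

infomax_epoch <- function(st, epoch) {
  Z <- st$Z; W <- st$W; K <- st$K
  W_old <- W
  ord <- st$perms[[epoch]]
  nb <- ceiling(st$p / st$batch_size)
  I_K <- diag(K)
  for (b in seq_len(nb)) {
    idx <- ord[((b - 1) * st$batch_size + 1):min(b * st$batch_size, st$p)]
    U <- W %*% Z[, idx, drop = FALSE]
    G <- 1 / (1 + exp(-U))
    delta <- st$lr * (I_K + ((1 - 2 * G) %*% t(U)) / length(idx)) %*% W
    W <- W + delta
    if (!all(is.finite(W))) {
      st$diverged <- TRUE
      st$W <- W
      st$epoch <- epoch
      return(st)
    }
  }
  # anneal when the epoch-level weight-change direction turns by > 60 deg;
  # once triggered, keep shrinking gently so the stochastic jitter decays
  delta_epoch <- W - W_old
  if (!is.null(st$prev_delta)) {
    num <- sum(delta_epoch * st$prev_delta)
    den <- sqrt(sum(delta_epoch^2) * sum(st$prev_delta^2))
    if (den > 0 && num / den < cos(60 * pi / 180)) {
      st$lr <- st$lr * 0.9
      st$annealing <- TRUE
    } else if (isTRUE(st$annealing)) {
      st$lr <- st$lr * 0.985
    }
  }
  st$prev_delta <- delta_epoch
  st$last_change <- norm(W - W_old, "F") / max(norm(W_old, "F"), 1e-12)
  st$changes <- c(st$changes, st$last_change)
  st$W <- W
  st$epoch <- epoch
  st
}

#' Least-squares loading coefficients
#'
#' Solves `X ~ loadings %*% sources` for the per-subject loading
#' coefficients given fixed sources, and records per-component
#' reconstruction R-squared.
#'
#' @param X subjects x features matrix.
#' @param sources K x features matrix, full row rank.
#' @return list(loadings = subjects x K, r2 = per-component R-squared of the
#'   rank-1 reconstruction terms against X).
#' @export
compute_loadings <- function(X, sources) {
  X <- as.matrix(X)
  S <- as.matrix(sources)
  if (nrow(S) == 0) {
    return(list(loadings = matrix(0, nrow(X), 0), r2 = numeric(0)))
  }
  G <- tcrossprod(S)
  if (qr(S)$rank < nrow(S)) stop_pf("sources are rank deficient")
  A <- X %*% t(S) %*% solve(G)
  tot <- sum(center_cols(X)^2)
  r2 <- vapply(seq_len(nrow(S)), function(k) {
    rec <- outer(A[, k], S[k, ])
    if (tot == 0) return(NA_real_)
    1 - sum((X - rec)^2) / max(sum(X^2), 1e-300)
  }, numeric(1))
  list(loadings = A, r2 = r2)
}
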