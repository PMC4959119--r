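# Leave-N-subjects-out stability of the Para-ICA solution.

#' Leave-N-out cross-validation of component stability
#'
#' Runs the full-sample Para-ICA once, then `repeats` times removes a
#' uniformly random `holdout_frac` of subjects (5% by default), reruns the
#' fusion under a derived seed, and matches the subsample sources to the
#' full-sample sources by optimal absolute-correlation assignment
#' ([match_components()]).  A component is declared stable when its mean
#' matched |correlation| across successful repeats is at least `tau_stab`;
#' the per-modality percent of stable components is the headline statistic.
#'
#' @param X_gene,X_brain subjects x features matrices (same rows).
#' @param fusion_config Named list of arguments for [run_para_ica()]
#'   (must include `K_gene`, `K_brain`).
#' @param holdout_frac Fraction of subjects removed per repeat.
#' @param repeats Number of subsample repeats (>= 2).
#' @param tau_stab Mean |correlation| threshold defining "stable".
#' @param seed Master seed for subsample draws and derived fusion seeds.
#' @return Object of class `stability_report`: per-modality data.frames
#'   (component, mean_abs_correlation, stable), `percent_stable`,
#'   `mean_correlation`, parameters, and the number of successful repeats.
#' @export
loo_stability <- function(X_gene, X_brain, fusion_config,
                          holdout_frac = 0.05, repeats = 10,
                          tau_stab = 0.8, seed = 1) {
  n <- nrow(X_gene)
  n_hold <- round(holdout_frac * n)
  if (n_hold < 1) stop_pf("holdout_frac * n_subjects must be >= 1")
  if (repeats < 2) stop_pf("need at least 2 repeats")

  full <- do.call(run_para_ica,
                  c(list(X_gene = X_gene, X_brain = X_brain), fusion_config))
  Kg <- ncol(full$gene_model$loadings)
  Kb <- ncol(full$brain_model$loadings)
  seeds <- matrix(derive_seeds(seed, 2 * repeats), ncol = 2)
  acc_g <- matrix(NA_real_, repeats, Kg)
  acc_b <- matrix(NA_real_, repeats, Kb)
  ok <- logical(repeats)
  for (rep_i in seq_len(repeats)) {
    hold <- with_seed(seeds[rep_i, 1], sample.int(n, n_hold))
    sub_cfg <- fusion_config
    sub_cfg$seed <- seeds[rep_i, 2]
    res <- tryCatch(
      do.call(run_para_ica, c(list(X_gene = X_gene[-hold, , drop = FALSE],
                                   X_brain = X_brain[-hold, , drop = FALSE]),
                              sub_cfg)),
      error = function(e) {
        warn_pf("stability repeat %d skipped: %s", rep_i, conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    ok[rep_i] <- TRUE
    mg <- match_components(full$gene_model$sources, res$gene_model$sources)
    mb <- match_components(full$brain_model$sources, res$brain_model$sources)
    acc_g[rep_i, as.integer(names(mg$matched_abs))] <- mg$matched_abs
    acc_b[rep_i, as.integer(names(mb$matched_abs))] <- mb$matched_abs
  }
  if (sum(ok) < 2) stop_pf("fewer than 2 successful stability repeats")

  summarise <- function(acc, K) {
    mean_abs <- colMeans(acc[ok, , drop = FALSE], na.rm = TRUE)
    data.frame(component = seq_len(K), mean_abs_correlation = mean_abs,
               stable = mean_abs >= tau_stab)
  }
  gene_tab <- summarise(acc_g, Kg)
  brain_tab <- summarise(acc_b, Kb)
  structure(list(
    gene = gene_tab, brain = brain_tab,
    percent_stable = c(gene = 100 * mean(gene_tab$stable),
                       brain = 100 * mean(brain_tab$stable)),
    mean_correlation = c(gene = mean(gene_tab$mean_abs_correlation),
                         brain = mean(brain_tab$mean_abs_correlation)),
    repeats = repeats, successful_repeats = sum(ok),
    holdout_frac = holdout_frac, tau_stab = tau_stab, seed = seed),
    class = "stability_report")
}
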