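# Gene-level interpretation: coordinate SNP->gene annotation, VEGAS-style
# Monte-Carlo gene-based p-values (gene-size corrected), dominant-gene
# selection, and hypergeometric pathway enrichment with BH FDR.

#' Annotate SNPs to genes by coordinate overlap
#'
#' Assigns every SNP to each gene whose 1-based inclusive `[start, end]`
#' interval contains its position (a SNP may land in several overlapping
#' genes).  Chromosome naming is normalised (`chr1` vs `1`).
#'
#' @param snp_records data.frame with `id`, `chrom`, `pos`.
#' @param gene_model data.frame with `symbol`, `chrom`, `start`, `end`.
#' @return list(assignments = data.frame(snp, gene), unassigned = SNP ids
#'   overlapping no gene).
#' @export
annotate_snps_to_genes <- function(snp_records, gene_model) {
  norm_chr <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)
  snps <- GenomicRanges::GRanges(
    seqnames = norm_chr(snp_records$chrom),
    ranges = IRanges::IRanges(start = snp_records$pos,
                              end = snp_records$pos))
  genes <- GenomicRanges::GRanges(
    seqnames = norm_chr(gene_model$chrom),
    ranges = IRanges::IRanges(start = gene_model$start,
                              end = gene_model$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snps, genes))
  assignments <- data.frame(
    snp = snp_records$id[S4Vectors::queryHits(hits)],
    gene = gene_model$symbol[S4Vectors::subjectHits(hits)])
  list(assignments = assignments,
       unassigned = setdiff(snp_records$id, assignments$snp))
}

#' Per-SNP p-values from component weights
#'
#' Standardises a component's SNP weight vector to z-scores over the
#' component and converts to two-sided normal p-values
#' `p = 2 Phi(-|z|)`.  Scale-invariant by construction.  (Externally
#' supplied trait p-values, e.g. from [logistic_prefilter()], can be used
#' with [gene_based_test()] directly instead.)
#'
#' @param gene_component_weights Numeric weight vector over SNPs.
#' @return Named numeric vector of p-values.
#' @export
component_snp_pvalues <- function(gene_component_weights) {
  w <- as.numeric(gene_component_weights)
  s <- sd(w)
  if (s == 0) stop_pf("zero-variance component weights")
  z <- (w - mean(w)) / s
  p <- 2 * pnorm(-abs(z))
  names(p) <- names(gene_component_weights)
  p
}

#' VEGAS-style Monte-Carlo gene-based test
#'
#' Gene statistic `T = sum_i qchisq(1 - p_i, df = 1)` over the gene's SNPs;
#' the null distribution draws `z ~ MVN(0, Sigma_LD)` (eigen-factor
#' sampling, so singular LD matrices are handled) and compares
#' `T' = sum z_i^2`.  The gene p-value is `(1 + #\{T' >= T\}) / (1 + n_sims)`
#' with Monte-Carlo standard error reported; `n_sims` escalates (doubling,
#' up to `max_sims`) while fewer than 10 exceedances are seen, so the
#' p-value floor is `1 / (1 + n_sims)`.  This corrects gene-size bias: the
#' null scales with the number (and LD) of SNPs in the gene.
#'
#' @param snp_pvalues p-values of the gene's SNPs.
#' @param ld_correlation SNP x SNP correlation matrix (PSD; small negative
#'   eigenvalues are repaired, large deviations fail).
#' @param n_sims Initial Monte-Carlo draws (>= 1000).
#' @param seed Integer seed.
#' @param max_sims Escalation ceiling.
#' @return list(T, p, se, n_sims, n_exceed).
#' @export
gene_based_test <- function(snp_pvalues, ld_correlation = NULL,
                            n_sims = 10000, seed = 1, max_sims = 200000) {
  p_in <- pmin(pmax(as.numeric(snp_pvalues), 1e-15), 1)
  m <- length(p_in)
  if (m == 0) stop_pf("no SNP p-values supplied")
  if (is.null(ld_correlation)) ld_correlation <- diag(m)
  Sigma <- as.matrix(ld_correlation)
  if (!identical(dim(Sigma), c(m, m))) stop_pf("LD matrix dimension mismatch")
  if (n_sims < 1000) stop_pf("n_sims must be >= 1000")
  T_obs <- sum(qchisq(1 - p_in, df = 1))

  es <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  adj <- sum(pmin(es$values, 0)^2)
  if (sqrt(adj) > 0.1 * m) {
    stop_pf("LD matrix far from positive semi-definite (adjustment %.3g)", sqrt(adj))
  }
  if (sqrt(adj) > 1e-8) {
    message(sprintf("LD matrix repaired to PSD (eigenvalue adjustment %.3g)", sqrt(adj)))
  }
  lam <- pmax(es$values, 0)
  Fac <- es$vectors %*% diag(sqrt(lam), m)   # draws = N(0, I) %*% t(Fac)

  sims <- 0L
  exceed <- 0L
  batch <- n_sims
  with_seed(seed, {
    repeat {
      Zn <- matrix(rnorm(batch * m), batch, m) %*% t(Fac)
      exceed <- exceed + sum(rowSums(Zn^2) >= T_obs)
      sims <- sims + batch
      if (exceed >= 10 || sims >= max_sims) break
      batch <- min(sims, max_sims - sims)
    }
  })
  p <- (1 + exceed) / (1 + sims)
  list(T = T_obs, p = p, se = sqrt(p * (1 - p) / sims), n_sims = sims,
       n_exceed = exceed)
}

#' Select dominant genes of a component
#'
#' Genes with gene-based p strictly below `alpha`, ascending by p.
#'
#' @param gene_pvalues Named vector of gene-level p-values.
#' @param alpha Selection threshold.
#' @return Character vector of gene names.
#' @export
select_component_genes <- function(gene_pvalues, alpha = 0.05) {
  stopifnot(all(gene_pvalues >= 0 & gene_pvalues <= 1, na.rm = TRUE))
  sel <- gene_pvalues[!is.na(gene_pvalues) & gene_pvalues < alpha]
  names(sel)[order(sel)]
}

#' Hypergeometric pathway enrichment with BH FDR
#'
#' For each pathway (intersected with the background) with at least one
#' overlapping query gene, computes the upper-tail hypergeometric
#' probability `P(X >= k)` of drawing `k` pathway genes in `n = |query|`
#' draws from `N = |background|` genes of which `K` are in the pathway,
#' then adjusts across tested pathways by Benjamini-Hochberg.
#'
#' @param query_genes Genes of interest (must all be in the background).
#' @param pathway_db Named list of gene sets (e.g. from [read_gmt()]).
#' @param background_genes The annotation universe.
#' @return data.frame of class `enrichment_result`: pathway, pathway_size,
#'   overlap, genes (semicolon-joined), p, q — sorted by p.
#' @export
hypergeometric_enrichment <- function(query_genes, pathway_db,
                                      background_genes) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  missing_q <- setdiff(query_genes, background_genes)
  if (length(missing_q) > 0) {
    stop_pf("query genes absent from background: %s",
            paste(head(missing_q, 5), collapse = ", "))
  }
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- list()
  for (pw in names(pathway_db)) {
    pset <- intersect(pathway_db[[pw]], background_genes)
    K <- length(pset)
    hit <- intersect(query_genes, pset)
    k <- length(hit)
    if (k < 1) next
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = pw, pathway_size = K, overlap = k,
      genes = paste(sort(hit), collapse = ";"), p = p)
  }
  if (length(rows) == 0) {
    out <- data.frame(pathway = character(0), pathway_size = integer(0),
                      overlap = integer(0), genes = character(0),
                      p = numeric(0), q = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out$q <- bh_fdr(out$p)
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) m / j`, capped at 1,
#' returned in input order.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return q-values, same order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}
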