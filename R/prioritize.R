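grid_alphas <- function(fits) {
  if (inherits(fits, "grid_fits"))
    list(alphas = lapply(fits$fits, `[[`, "alpha"), weights = fits$weights)
  else if (is.list(fits) && !is.null(fits$alphas)) fits
  else list(alphas = fits, weights = NULL)
}

check_locus <- function(locus, p) {
  locus <- as.integer(locus)
  if (length(locus) && (min(locus) < 1L || max(locus) > p))
    stop("locus references unknown SNP index (valid range 1..", p, ")")
  locus
}

#' Posterior probability that a locus harbors at least one associated SNP
#'
#' \deqn{P_1 = 1 - \sum_g w_g \prod_{j \in \mathrm{locus}} (1 - \alpha_j^{(g)}),}
#' i.e. one minus the posterior probability that every SNP effect in the
#' locus is zero, mixing over the hyperparameter grid posterior.  Within
#' each grid point the variational posterior factorizes over SNPs, which is
#' what makes the product form exact under the approximation.
#'
#' @param fits A `grid_fits` object, or a list of per-grid-point `alpha`
#'   vectors.
#' @param grid_weights Normalized grid posterior weights (taken from `fits`
#'   when it is a `grid_fits`).
#' @param locus Integer vector of SNP indices (typically from
#'   [build_gene_loci()]); an empty locus gives 0.
#' @return Scalar in `[0, 1]`.
#' @export
locus_p1 <- function(fits, grid_weights = NULL, locus) {
  ga <- grid_alphas(fits)
  w <- grid_weights %||% ga$weights
  stopifnot(!is.null(w), abs(sum(w) - 1) < 1e-6)
  locus <- check_locus(locus, length(ga$alphas[[1]]))
  if (!length(locus)) return(0)
  pr_none <- vapply(ga$alphas, function(a) prod(1 - a[locus]), 0)
  1 - sum(w * pr_none)
}

#' Posterior expected number of associated SNPs in a locus
#'
#' \deqn{\mathrm{ENS} = \sum_g w_g \sum_{j \in \mathrm{locus}} \alpha_j^{(g)}.}
#' Always at least as large as [locus_p1()] on the same locus.
#'
#' @inheritParams locus_p1
#' @return Scalar `>= 0`.
#' @export
locus_ens <- function(fits, grid_weights = NULL, locus) {
  ga <- grid_alphas(fits)
  w <- grid_weights %||% ga$weights
  stopifnot(!is.null(w), abs(sum(w) - 1) < 1e-6)
  locus <- check_locus(locus, length(ga$alphas[[1]]))
  if (!length(locus)) return(0)
  sum(w * vapply(ga$alphas, function(a) sum(a[locus]), 0))
}

#' Gene-level association report under baseline and enrichment models
#'
#' For each gene locus, computes P1 and ENS under the baseline posterior
#' (M0) and under the enrichment posterior (M1).  Differences between the
#' two reflect the influence of the inferred enrichment on that gene's
#' association evidence.  Genes with enrichment `P1 > 0.9` are flagged as
#' signals.  Sorted by `P1_enrichment` descending, ties broken by
#' `ENS_enrichment` then gene name, so the ordering is deterministic.
#'
#' @param baseline_posterior `grid_fits` from [fit_baseline_grid()].
#' @param enrichment_posterior `grid_fits` from [fit_enrichment_grid()].
#' @param loci Named list of SNP-index vectors from [build_gene_loci()].
#' @return data.frame with one row per gene: `gene`, `n_snps`,
#'   `P1_baseline`, `P1_enrichment`, `ENS_baseline`, `ENS_enrichment`,
#'   `signal`.
#' @export
gene_report <- function(baseline_posterior, enrichment_posterior, loci) {
  stopifnot(length(loci) >= 1, !is.null(names(loci)))
  rep_df <- data.frame(
    gene = names(loci),
    n_snps = lengths(loci),
    P1_baseline = vapply(loci, function(l) locus_p1(baseline_posterior, locus = l), 0),
    P1_enrichment = vapply(loci, function(l) locus_p1(enrichment_posterior, locus = l), 0),
    ENS_baseline = vapply(loci, function(l) locus_ens(baseline_posterior, locus = l), 0),
    ENS_enrichment = vapply(loci, function(l) locus_ens(enrichment_posterior, locus = l), 0),
    stringsAsFactors = FALSE)
  rep_df$signal <- rep_df$P1_enrichment > 0.9
  o <- order(-rep_df$P1_enrichment, -rep_df$ENS_enrichment, rep_df$gene)
  rep_df <- rep_df[o, , drop = FALSE]
  rownames(rep_df) <- NULL
  rep_df
}
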