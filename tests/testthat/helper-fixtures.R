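# Shared in-code fixtures; everything is generated, nothing read from disk.

# wrap a dense symmetric PD correlation matrix as a one-block banded_ld
toy_ld <- function(R, chrom = "1", pos = NULL) {
  p <- ncol(R)
  pos <- pos %||% (seq_len(p) * 10000L)
  structure(list(
    blocks = list(list(chrom = chrom, idx = seq_len(p),
                       band = gsenrich:::dense_to_band(R, p - 1L),
                       bw = p - 1L, lambda = 0)),
    p = p, snp = data.frame(chrom = rep(chrom, p), pos = pos),
    ext = rep(p - 1L, p), bandwidth_cm = Inf),
    class = "banded_ld")
}

toy_stats <- function(betahat, se, n = 1000, chrom = "1", pos = NULL,
                      a1 = "C", a2 = "A") {
  p <- length(betahat)
  data.frame(snp_id = sprintf("rs%04d", seq_len(p)), chrom = rep(chrom, p),
             pos = pos %||% (seq_len(p) * 10000L),
             allele_effect = rep(a1, p), allele_other = rep(a2, p),
             betahat = betahat, se = se, n = rep(n, length.out = p),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_pd_corr <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 2L)), p + 2L, p)
  stats::cov2cor(crossprod(A) / (p + 1L))
}

# a small end-to-end study, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_cache$study)) {
    sc <- sim_scenario("sparse", "a", n = 1200, p = 800, theta = 2, h = 0.3,
                       n_genes = 25, set_fraction = 0.08, n_panel_hap = 300)
    study <- simulate_study(sc, "enrichment", seed = 101)
    ld <- estimate_shrunk_ld(study$panel, map = study$map)
    .fixture_cache$study <- list(study = study, ld = ld,
                                 canon = to_canonical(study$stats, ld))
  }
  .fixture_cache$study
}

acc_grid0 <- function() make_grid(seq(-4.5, -2, 0.5), 0, c(0.1, 0.3, 0.5))
acc_grid1 <- function() make_grid(seq(-4.5, -2, 0.5), seq(0.5, 3, 0.5),
                                  c(0.1, 0.3, 0.5))

# coarser grid used for the many-dataset benchmark sweeps
bench_grid0 <- function() make_grid(c(-3.5, -3, -2.5, -2), 0, c(0.2, 0.4))
bench_grid1 <- function() make_grid(c(-3.5, -3, -2.5, -2), c(1, 2, 3),
                                    c(0.2, 0.4))

# full pipeline: simulated study -> LD -> canonical -> enrichment result
study_enrichment <- function(study, grid0, grid1, seed = 42) {
  ld <- estimate_shrunk_ld(study$panel, map = study$map)
  canon <- to_canonical(study$stats, ld)
  test_enrichment(canon, study$annotation, grid0, grid1, seed = seed)
}

# draw one small instance from the summary-statistic likelihood itself
sample_instance <- function(p, seed, enriched = NA) {
  set.seed(seed)
  R <- rand_pd_corr(p, seed = seed + 5000L)
  se <- runif(p, 0.05, 0.15)
  a <- as.integer(seq_len(p) <= p / 2)
  beta <- numeric(p)
  if (is.na(enriched)) enriched <- runif(1) < 0.5
  pool <- if (enriched) which(a == 1) else which(a == 0)
  idx <- sample(pool, min(2L, length(pool)))
  beta[idx] <- rnorm(length(idx), 0, 0.25)
  S <- diag(se, p)
  SRS <- S %*% R %*% S
  mean_bh <- S %*% R %*% diag(1 / se, p) %*% beta
  bhat <- drop(mean_bh + t(chol(SRS)) %*% rnorm(p))
  list(stats = toy_stats(bhat, se), ld = toy_ld(R), a = a, enriched = enriched)
}

# oracle log10 BF by enumeration, averaging evidence over small grids
oracle_log10_bf <- function(inst, grid0, grid1) {
  m_of <- function(grid, ann) {
    vapply(seq_len(nrow(grid)), function(g) {
      pr <- prior_spec(grid$theta0[g], grid$theta[g], grid$h[g], ann,
                       inst$stats)
      exact_log_marginal_oracle(inst$stats, inst$ld, pr$pi, pr$sigma_beta2)
    }, 0)
  }
  b0 <- m_of(grid0, NULL)
  b1 <- m_of(grid1, inst$a)
  log10_bf(b0, b1)
}

# variational log10 BF on the same instance and grids
vb_log10_bf <- function(inst, grid0, grid1, seed = 42) {
  canon <- to_canonical(inst$stats, inst$ld)
  base <- fit_baseline_grid(canon, grid0, seed = seed, tol = 1e-6,
                            max_iter = 500)
  enr <- fit_enrichment_grid(canon, grid1, inst$a, base, reuse = FALSE,
                             tol = 1e-6, max_iter = 500)
  log10_bf(base, enr)
}
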