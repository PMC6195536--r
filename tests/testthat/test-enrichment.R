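test_that("grid posterior weights normalize and are shift-invariant", {
  expect_equal(gsenrich:::softmax_weights(5), 1)
  expect_equal(gsenrich:::softmax_weights(c(3, 3)), c(0.5, 0.5))
  b <- c(-10, -12, -9.5)
  expect_equal(gsenrich:::softmax_weights(b),
               gsenrich:::softmax_weights(b + 1000))
  expect_equal(sum(gsenrich:::softmax_weights(rnorm(20))), 1)
})

test_that("log10 BF reduces to simple closed forms on matched bounds", {
  b0 <- c(-100, -101, -99)
  expect_equal(log10_bf(b0, b0), 0)
  expect_equal(log10_bf(b0, b0 + log(10)), 1)
  expect_equal(log10_bf(b0, b0 - 2 * log(10)), -2)
  # invariant to uniform scaling of the grid prior: replicating every M1
  # point leaves the mean evidence unchanged
  expect_equal(log10_bf(b0, rep(b0, 3)), 0)
})

test_that("hyperparameter posteriors summarize the grid correctly", {
  g <- make_grid(-3, 1.5, 0.3)
  post <- hyperparam_posterior(0, g)
  expect_equal(post$table$weight, 1)
  th <- post$summary[post$summary$param == "theta", ]
  expect_equal(c(th$mean, th$lower, th$upper), c(1.5, 1.5, 1.5))
  # symmetric bounds over a symmetric theta0 grid center the posterior
  g2 <- make_grid(c(-4, -3, -2), 1, 0.3)
  post2 <- hyperparam_posterior(c(-5, -4, -5), g2)
  expect_equal(post2$summary$mean[post2$summary$param == "theta0"], -3,
               tolerance = 1e-12)
})

test_that("baseline grid fitting weights points by their evidence", {
  fx <- small_study()
  g0 <- make_grid(c(-3.5, -2.5), 0, c(0.2, 0.4))
  bf <- fit_baseline_grid(fx$canon, g0, seed = 42)
  expect_s3_class(bf, "grid_fits")
  expect_equal(sum(bf$weights), 1)
  expect_length(bf$fits, 4)
  expect_true(all(is.finite(bf$bounds)))
  # single-point grid gets weight 1
  b1 <- fit_baseline_grid(fx$canon, make_grid(-3, 0, 0.3), seed = 42)
  expect_equal(b1$weights, 1)
  expect_error(fit_baseline_grid(fx$canon, make_grid(-3, 1, 0.3)),
               "theta = 0")
})

test_that("enrichment fits reuse baselines and match full refits closely", {
  fx <- small_study()
  g0 <- make_grid(c(-3.5, -2.5), 0, c(0.2, 0.4))
  g1 <- make_grid(c(-3.5, -2.5), c(1, 2), c(0.2, 0.4))
  base <- fit_baseline_grid(fx$canon, g0, seed = 42)
  enr_reuse <- fit_enrichment_grid(fx$canon, g1, fx$study$annotation, base)
  enr_full <- fit_enrichment_grid(fx$canon, g1, fx$study$annotation, base,
                                  reuse = FALSE)
  bf_reuse <- log10_bf(base, enr_reuse)
  bf_full <- log10_bf(base, enr_full)
  expect_lt(abs(bf_reuse - bf_full), 0.1)
  expect_error(fit_enrichment_grid(fx$canon, g1, rep(0, fx$canon$p), base),
               "empty")
  expect_error(fit_enrichment_grid(fx$canon, make_grid(-5, 1, 0.2),
                                   fx$study$annotation, base),
               "lack")
})

test_that("an annotation disjoint from the signal loses evidence at high theta", {
  fx <- small_study()
  # decoy annotation: SNPs far from every causal SNP
  causal <- fx$study$truth$causal_snps
  far <- setdiff(seq_len(fx$canon$p), unlist(lapply(causal, function(j)
    max(1, j - 30):min(fx$canon$p, j + 30))))
  a <- integer(fx$canon$p); a[sample(far, 50)] <- 1L
  g0 <- make_grid(-3, 0, 0.3)
  base <- fit_baseline_grid(fx$canon, g0, seed = 42)
  enr <- fit_enrichment_grid(fx$canon, make_grid(-3, 3, 0.3), a, base)
  expect_lt(enr$bounds[1], base$bounds[1])
})

test_that("test_enrichment detects the simulated target-set enrichment", {
  fx <- small_study()
  g0 <- acc_grid0(); g1 <- acc_grid1()
  res <- test_enrichment(fx$canon, fx$study$annotation, g0, g1, seed = 42)
  expect_s3_class(res, "enrichment_result")
  expect_gt(res$log10_bf, 1)
  expect_gt(res$theta_mean, 0.5)
  expect_true(is.finite(res$log10_bf))
  # theta = 0 requested inside the enrichment grid reuses the baseline fit
  gmix <- make_grid(-3, 0, 0.3)
  class(gmix) <- class(g1)
  enr0 <- fit_enrichment_grid(fx$canon, gmix, fx$study$annotation,
                              res$baseline)
  i0 <- match(paste(-3, 0.3), paste(g0$theta0, g0$h))
  expect_identical(enr0$fits[[1]]$alpha, res$baseline$fits[[i0]]$alpha)
})

test_that("z-score mixture LR check separates enriched from matched groups", {
  set.seed(33)
  # identical groups: LR at numerical zero
  z <- rnorm(500)
  same <- zscore_lr_check(z, z)
  expect_lt(same$lr, 1e-6)
  # clearly different mixtures
  z_in <- ifelse(runif(2000) < 0.2, rnorm(2000, 0, sqrt(10)), rnorm(2000))
  z_out <- ifelse(runif(2000) < 0.01, rnorm(2000, 0, sqrt(10)), rnorm(2000))
  diff <- zscore_lr_check(z_in, z_out)
  expect_gt(diff$lr, 10)
  # symmetric model: invariant to sign-flipping all z-scores
  flip <- zscore_lr_check(-z_in, -z_out)
  expect_equal(flip$lr, diff$lr, tolerance = 1e-6)
  expect_warning(zscore_lr_check(rnorm(5), rnorm(50)), "fewer than 10")
})

test_that("the sanity suite flags weak sets and is seed-deterministic", {
  fx <- small_study()
  g0 <- make_grid(c(-3.5, -2.5), 0, 0.3)
  g1 <- make_grid(c(-3.5, -2.5), c(1, 2), 0.3)
  res <- test_enrichment(fx$canon, fx$study$annotation, g0, g1, seed = 42)
  checked <- run_sanity_suite(res, fx$canon, fx$study$annotation,
                              fx$study$genes, fx$study$stats, seed = 7, k = 5)
  expect_true(checked$flags$generic_genic %in% c("pass", "warn"))
  expect_true(checked$flags$null_sets %in% c("pass", "warn"))
  expect_length(checked$flags$null_bfs, 5)
  expect_type(checked$flags$lr_check$lr, "double")
  checked2 <- run_sanity_suite(res, fx$canon, fx$study$annotation,
                               fx$study$genes, fx$study$stats, seed = 7, k = 5)
  expect_identical(checked$flags$null_bfs, checked2$flags$null_bfs)
  # the true target set outranks size-matched null draws
  expect_equal(checked$flags$null_sets, "pass")
})
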