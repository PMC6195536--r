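test_that("genotype simulation respects seed, MAF bounds and LD decay", {
  g1 <- simulate_genotypes(200, 50, seed = 3)
  g2 <- simulate_genotypes(200, 50, seed = 3)
  expect_identical(g1$geno, g2$geno)
  expect_true(all(g1$maf >= 0.05 & g1$maf <= 0.5))
  expect_true(all(g1$geno %in% 0:2))
  # ld_decay = 0: independent SNPs, mean adjacent |r| small
  g0 <- simulate_genotypes(2000, 200, ld_decay = 0, seed = 4)
  r_adj <- vapply(1:199, function(j) cor(g0$geno[, j], g0$geno[, j + 1]), 0)
  expect_lt(mean(abs(r_adj)), 0.05)
  # strong decay produces strong adjacent correlation
  g9 <- simulate_genotypes(2000, 50, ld_decay = 0.95, seed = 5)
  r9 <- vapply(1:49, function(j) cor(g9$geno[, j], g9$geno[, j + 1]), 0)
  expect_gt(mean(r9), 0.5)
})

test_that("effect draws follow the enrichment prior across scenarios", {
  sc <- sim_scenario("sparse", "a", n = 100, p = 2000, theta = 2, h = 0.3)
  a <- integer(2000); a[1:200] <- 1L
  geno <- simulate_genotypes(100, 2000, seed = 6)$geno
  # theta -> infinity: essentially every causal SNP is inside
  sc_inf <- sim_scenario("sparse", "a", n = 100, p = 2000, theta = 12, h = 0.3)
  set.seed(8)
  eff <- draw_effects(sc_inf, a, geno)
  expect_true(all(a[eff$causal] == 1))
  # expected causal count is matched in expectation
  expect_equal(sum(eff$pi), 50, tolerance = 1e-6)
  set.seed(9)
  effp <- draw_effects(sim_scenario("polygenic", "a", n = 100, p = 2000,
                                    theta = 0, h = 0.3), NULL, geno)
  expect_equal(sum(effp$pi), 20, tolerance = 1e-6)  # 1% of p
  # theta = 0: inside/outside causal fractions equal within binomial error
  set.seed(10)
  frac_in <- frac_out <- numeric(50)
  sc0 <- sim_scenario("polygenic", "a", n = 100, p = 2000, theta = 0, h = 0.3)
  for (i in 1:50) {
    e <- draw_effects(sc0, NULL, geno)
    frac_in[i] <- mean(seq_len(2000) %in% e$causal & a == 1) / mean(a)
    frac_out[i] <- mean(seq_len(2000) %in% e$causal & a == 0) / mean(1 - a)
  }
  se_diff <- sqrt(var(frac_in - frac_out) / 50)
  expect_lt(abs(mean(frac_in) - mean(frac_out)), 4 * se_diff + 1e-3)
  # pattern d with multiplier 1 reduces to pattern a (identical draws)
  scd <- sim_scenario("sparse", "d", n = 100, p = 2000, theta = 2, h = 0.3,
                      effect_multiplier = 1.5)
  set.seed(11); ed1 <- draw_effects(scd, a, geno, multiplier = 1)
  set.seed(11); ea <- draw_effects(sc, a, geno, multiplier = 1)
  expect_identical(ed1$beta, ea$beta)
  # multiplier inflates inside-set effect scale
  set.seed(11); ed <- draw_effects(scd, a, geno, multiplier = 1.5)
  expect_identical(ed$causal, ed1$causal)
  inside <- a[ed$causal] == 1
  expect_equal(ed$beta[ed$causal][inside], 1.5 * ed1$beta[ed1$causal][inside])
  expect_equal(ed$beta[ed$causal][!inside], ed1$beta[ed1$causal][!inside])
})

test_that("single-SNP summary statistics match the least-squares oracle", {
  set.seed(15)
  geno <- simulate_genotypes(80, 6, seed = 15)$geno
  y <- rnorm(80)
  st <- single_snp_summary_stats(geno, y)
  for (j in 1:6) {
    fit <- summary(lm(y ~ geno[, j]))$coefficients
    expect_equal(st$betahat[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(st$se[j], fit[2, 2], tolerance = 1e-10)
  }
  # perfect fit: residual zero, se floored and flagged
  y2 <- 2.5 * geno[, 1]
  st2 <- single_snp_summary_stats(geno, y2)
  expect_equal(st2$betahat[1], 2.5)
  expect_equal(st2$se[1], 1e-12)
  expect_gte(attr(st2, "se_floored"), 1)
})

test_that("null phenotypes give standard-normal z-scores", {
  set.seed(16)
  geno <- simulate_genotypes(500, 400, ld_decay = 0.3, seed = 16)$geno
  z <- unlist(lapply(1:4, function(i) {
    st <- single_snp_summary_stats(geno, sample(rnorm(500)))
    st$betahat / st$se
  }))
  # mean |z| of N(0,1) is sqrt(2/pi); MC standard error of the mean
  se_mc <- sd(abs(z)) / sqrt(length(z))
  expect_lt(abs(mean(abs(z)) - sqrt(2 / pi)), 3 * se_mc + 0.02)
  expect_lt(abs(var(z) - 1), 0.15)
})

test_that("rank AUC agrees with exhaustive pair counting and its edge cases", {
  expect_equal(evaluate_auc(c(1, 2, 3), c(4, 5, 6)), 1.0)
  expect_equal(evaluate_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  s0 <- c(0.1, 0.5, 0.9); s1 <- c(0.2, 0.5, 1.4)
  wins <- 0
  for (i in 1:3) for (j in 1:3)
    wins <- wins + (s1[i] > s0[j]) + 0.5 * (s1[i] == s0[j])
  expect_equal(evaluate_auc(s0, s1), wins / 9)
})

test_that("simulated studies carry coherent truth labels and fixtures round-trip", {
  sc <- sim_scenario("sparse", "a", n = 300, p = 400, theta = 2, h = 0.3,
                     n_genes = 20, n_panel_hap = 200)
  study <- simulate_study(sc, "enrichment", seed = 21)
  expect_s3_class(study, "sim_study")
  expect_equal(nrow(study$stats), 400)
  # a gene is associated iff a causal SNP lies within the window of its span
  w <- sc$window
  for (i in seq_len(nrow(study$genes))) {
    has <- any(study$stats$pos[study$truth$causal_snps] >=
                 study$genes$start[i] - w &
               study$stats$pos[study$truth$causal_snps] <=
                 study$genes$end[i] + w)
    expect_equal(study$genes$gene[i] %in% study$truth$associated_genes, has)
  }
  # summary statistics are reproducible from genotypes + phenotype
  st2 <- single_snp_summary_stats(study$geno, study$phenotype,
                                  snp_info = study$panel$snp)
  expect_equal(st2$betahat, study$stats$betahat)
  # the written fixture re-reads into the same objects
  dir <- withr::local_tempdir()
  paths <- write_study_fixture(study, dir)
  st_rt <- read_summary_stats(paths["stats"])
  expect_equal(st_rt$betahat, study$stats$betahat)
  panel_rt <- load_reference_panel(paths["panel"])
  expect_equal(unname(colSums(panel_rt$geno)), unname(colSums(study$panel$geno)))
  genes_rt <- read_gene_annotations(paths["genes"])
  expect_equal(sort(genes_rt$gene), sort(study$genes$gene))
  expect_equal(genes_rt$start[order(genes_rt$gene)],
               study$genes$start[order(study$genes$gene)])
  sets_rt <- read_gene_sets(paths["sets"])
  expect_equal(sets_rt$target_set, study$gene_set)
  truth_rt <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth_rt$causal_snps, study$truth$causal_snps)
})
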