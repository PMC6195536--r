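test_that("banded storage round-trips through dense form", {
  R <- rand_pd_corr(8, seed = 3)
  band <- gsenrich:::dense_to_band(R, 7L)
  expect_equal(gsenrich:::band_to_dense(band), R)
  # truncating the band zeroes distant entries symmetrically
  band2 <- gsenrich:::dense_to_band(R, 2L)
  D <- gsenrich:::band_to_dense(band2)
  expect_equal(D[1, 2], R[1, 2])
  expect_equal(D[1, 4], 0)
  expect_equal(D, t(D))
})

test_that("band extents follow the genetic map with the 1 Mb fallback", {
  pos <- seq(1e6, 10e6, by = 1e6)
  chrom <- rep("1", 10)
  # uniform 1 cM/Mb map, bandwidth 1 cM -> each SNP reaches its neighbor
  mp <- data.frame(pos = c(0, 11e6), cm = c(0, 11))
  bw <- bandwidth_from_map(pos, chrom, mp, bandwidth_cm = 1)
  expect_equal(bw$ext[1:9], rep(1L, 9))
  expect_equal(bw$ext[10], 0L)
  # no map: identical extents via the 1 cM/Mb physical fallback
  bw2 <- bandwidth_from_map(pos, chrom, NULL, bandwidth_cm = 1)
  expect_equal(bw2$ext, bw$ext)
  # two chromosomes yield at least two independent blocks
  bw3 <- bandwidth_from_map(c(pos, pos), c(chrom, rep("2", 10)))
  expect_gte(nrow(bw3$blocks), 2)
  expect_error(bandwidth_from_map(pos, chrom,
                                  data.frame(pos = c(0, 5e6, 11e6),
                                             cm = c(0, 3, 2))),
               "monotone")
})

test_that("zero map distance leaves entries unshrunk and banding is exact", {
  gs <- simulate_genotypes(400, 40, ld_decay = 0.7, seed = 5)
  panel <- simulate_panel(gs, n_hap = 200, seed = 6, ld_decay = 0.7)
  ld <- estimate_shrunk_ld(panel, map = gs$map, bandwidth_cm = 0.1)
  blk <- ld$blocks[[1]]
  # entries beyond the 0.1 cM (= 10 SNP) bandwidth are exactly zero
  D <- gsenrich:::band_to_dense(blk$band)
  expect_true(all(D[abs(row(D) - col(D)) > 10] == 0))
  expect_equal(diag(D), rep(1, 40))
  expect_true(all(abs(D) <= 1 + 1e-12))
})

test_that("shrinkage decays monotonically with map distance", {
  m_hap <- 200
  d <- seq(0, 5, by = 0.25)
  fac <- exp(-(4 * 11418 * d / 100) / (2 * m_hap))
  expect_equal(fac[1], 1)
  expect_true(all(diff(fac) < 0))
  # two panels identical except for map scale: wider map shrinks more
  gs <- simulate_genotypes(300, 20, ld_decay = 0.8, seed = 9)
  panel <- simulate_panel(gs, n_hap = 150, seed = 10, ld_decay = 0.8)
  map_wide <- data.frame(pos = gs$map$pos, cm = gs$map$cm * 50)
  ld_near <- estimate_shrunk_ld(panel, map = gs$map, mutation_adjust = FALSE)
  ld_far <- estimate_shrunk_ld(panel, map = map_wide, bandwidth_cm = 50,
                               mutation_adjust = FALSE)
  b_near <- abs(ld_near$blocks[[1]]$band[2, 1:19])
  b_far <- abs(ld_far$blocks[[1]]$band[2, 1:19])
  expect_true(all(b_far <= b_near + 1e-12))
})

test_that("no shrinkage and infinite bandwidth recover the sample correlation", {
  gs <- simulate_genotypes(500, 30, ld_decay = 0.6, seed = 7)
  panel <- simulate_panel(gs, n_hap = 200, seed = 8, ld_decay = 0.6)
  ld <- estimate_shrunk_ld(panel, map = NULL, bandwidth_cm = 1e9, ne = 0,
                           mutation_adjust = FALSE)
  expect_length(ld$blocks, 1)
  R <- gsenrich:::band_to_dense(ld$blocks[[1]]$band)
  expect_equal(R, unname(cor(panel$geno)), tolerance = 1e-12)
})

test_that("estimated LD blocks are positive-definite (dense eigen oracle)", {
  gs <- simulate_genotypes(300, 50, ld_decay = 0.9, seed = 11)
  panel <- simulate_panel(gs, n_hap = 100, seed = 12, ld_decay = 0.9)
  ld <- estimate_shrunk_ld(panel, map = gs$map)
  rep <- validate_psd(ld)
  expect_true(all(rep$pd))
  for (blk in ld$blocks) {
    ev <- eigen(gsenrich:::band_to_dense(blk$band), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("validate_psd reports an identity band and flags rank deficiency", {
  ident <- toy_ld(diag(5))
  expect_equal(validate_psd(ident)$min_eig, 1)
  # rank-deficient toy: two perfectly correlated SNPs
  R <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_false(validate_psd(toy_ld(R))$pd)
})

test_that("banded Cholesky matches dense Cholesky", {
  R <- rand_pd_corr(12, seed = 21)
  band <- gsenrich:::dense_to_band(R, 11L)
  ch <- gsenrich:::.band_chol(band)
  expect_true(ch$ok)
  expect_equal(ch$logdet, as.numeric(determinant(R)$modulus), tolerance = 1e-10)
  b <- rnorm(12)
  expect_equal(gsenrich:::.band_chol_solve(ch$L, b), solve(R, b),
               tolerance = 1e-10)
  expect_false(gsenrich:::.band_chol(gsenrich:::dense_to_band(
    matrix(c(1, 2, 2, 1), 2, 2), 1L))$ok)
})
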