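test_that("canonical form reproduces the likelihood density up to a constant", {
  # p = 1: density equals Normal(betahat; beta, se^2) for every beta
  st1 <- toy_stats(0.3, 0.1)
  ld1 <- toy_ld(diag(1))
  cn1 <- to_canonical(st1, ld1)
  for (beta in c(-0.5, 0, 0.2, 1)) {
    expect_equal(cn1$logn0 + beta * cn1$q - 0.5 * beta^2 / 0.1^2,
                 dnorm(0.3, beta, 0.1, log = TRUE), tolerance = 1e-12)
  }
  expect_equal(cn1$logn0, dnorm(0.3, 0, 0.1, log = TRUE))
  # p = 3 random PD LD: canonical minus direct log-density is constant in beta
  R <- rand_pd_corr(3, seed = 2)
  st <- toy_stats(c(0.1, -0.2, 0.05), c(0.1, 0.12, 0.08))
  cn <- to_canonical(st, toy_ld(R))
  S <- diag(st$se)
  SRS <- S %*% R %*% S
  A <- S %*% R %*% diag(1 / st$se)
  H <- diag(1 / st$se) %*% R %*% diag(1 / st$se)
  set.seed(4)
  for (i in 1:10) {
    beta <- rnorm(3, 0, 0.1)
    resid <- st$betahat - A %*% beta
    direct <- -0.5 * (3 * log(2 * pi) + determinant(SRS)$modulus[1] +
                        t(resid) %*% solve(SRS, resid))
    canonical <- cn$logn0 + sum(beta * cn$q) - 0.5 * t(beta) %*% H %*% beta
    expect_equal(as.numeric(direct), as.numeric(canonical), tolerance = 1e-10)
  }
  expect_error(to_canonical(toy_stats(0.1, 0), toy_ld(diag(1))), "positive")
})

test_that("single-SNP fit matches the two-component closed form to 1e-8", {
  st <- toy_stats(0.3, 0.1)
  cn <- to_canonical(st, toy_ld(diag(1)))
  pi <- 0.1; sb2 <- 0.04
  pr <- structure(list(theta0 = NA, theta = NA, h = NA, pi = pi,
                       sigma_beta2 = sb2), class = "prior_spec")
  f <- vb_fit(cn, pr, init = list(alpha = 0.5, mu = 0), tol = 1e-12)
  m1 <- dnorm(0.3, 0, sqrt(0.1^2 + sb2))
  m0 <- dnorm(0.3, 0, 0.1)
  s2_exact <- sb2 * 0.01 / (sb2 + 0.01)
  expect_equal(f$alpha, pi * m1 / (pi * m1 + (1 - pi) * m0), tolerance = 1e-8)
  expect_equal(f$mu, s2_exact * 0.3 / 0.01, tolerance = 1e-8)
  expect_equal(f$s2, s2_exact, tolerance = 1e-8)
  # factorized family is exact at p = 1: bound equals the log marginal
  expect_equal(f$lower_bound, log(pi * m1 + (1 - pi) * m0), tolerance = 1e-8)
  expect_equal(exact_log_marginal_oracle(st, toy_ld(diag(1)), pi, sb2),
               log(pi * m1 + (1 - pi) * m0), tolerance = 1e-10)
})

test_that("limits and degenerate fixed points behave as expected", {
  st <- toy_stats(c(0.3, -0.1), c(0.1, 0.1))
  cn <- to_canonical(st, toy_ld(diag(2)))
  # pi -> 0: alpha -> 0
  pr0 <- structure(list(pi = rep(1e-12, 2), sigma_beta2 = 0.04,
                        theta0 = NA, theta = NA, h = NA), class = "prior_spec")
  f0 <- vb_fit(cn, pr0, init = list(alpha = c(0.5, 0.5), mu = c(0, 0)))
  expect_lt(max(f0$alpha), 1e-6)
  # zero signal: mu = 0 and alpha at the symmetric fixed point
  stz <- toy_stats(c(0, 0, 0), c(0.1, 0.2, 0.15))
  cnz <- to_canonical(stz, toy_ld(diag(3)))
  pi <- c(0.2, 0.3, 0.1); sb2 <- 0.05
  prz <- structure(list(pi = pi, sigma_beta2 = sb2, theta0 = NA, theta = NA,
                        h = NA), class = "prior_spec")
  fz <- vb_fit(cnz, prz, init = list(alpha = pi, mu = rep(0, 3)), tol = 1e-12)
  s2 <- sb2 / (sb2 / stz$se^2 + 1)
  expect_equal(fz$mu, rep(0, 3), tolerance = 1e-12)
  expect_equal(fz$alpha,
               plogis(qlogis(pi) + 0.5 * log(s2 / sb2)), tolerance = 1e-10)
})

test_that("diagonal H reaches its fixed point in one pass, in either order", {
  st <- toy_stats(c(0.2, -0.3, 0.1, 0), c(0.1, 0.08, 0.12, 0.1))
  cn <- to_canonical(st, toy_ld(diag(4)))
  pr <- structure(list(pi = rep(0.2, 4), sigma_beta2 = 0.03, theta0 = NA,
                       theta = NA, h = NA), class = "prior_spec")
  init <- list(alpha = rep(0.5, 4), mu = rep(0.1, 4), s2 = rep(1, 4),
               lower_bound = NA)
  p1 <- vb_coordinate_pass(init, cn, pr, "forward")
  p2 <- vb_coordinate_pass(p1, cn, pr, "forward")
  expect_equal(p1$alpha, p2$alpha, tolerance = 1e-12)
  expect_equal(p1$mu, p2$mu, tolerance = 1e-12)
  pb <- vb_coordinate_pass(init, cn, pr, "backward")
  expect_equal(p1$alpha, pb$alpha, tolerance = 1e-12)
})

test_that("the lower bound is monotone across plain coordinate passes", {
  set.seed(31)
  R <- rand_pd_corr(20, seed = 31)
  st <- toy_stats(rnorm(20, 0, 0.05), runif(20, 0.05, 0.15))
  cn <- to_canonical(st, toy_ld(R))
  pr <- structure(list(pi = rep(0.1, 20), sigma_beta2 = 0.02, theta0 = NA,
                       theta = NA, h = NA), class = "prior_spec")
  fit <- list(alpha = runif(20), mu = rnorm(20, 0, 0.1))
  bounds <- numeric(12)
  for (i in 1:12) {
    fit <- vb_coordinate_pass(fit, cn, pr,
                              if (i %% 2) "forward" else "backward")
    bounds[i] <- fit$lower_bound
  }
  expect_true(all(diff(bounds) > -1e-9))
})

test_that("acceleration reaches the same fixed point as plain updates", {
  set.seed(42)
  R <- rand_pd_corr(50, seed = 42)
  st <- toy_stats(rnorm(50, 0, 0.06), runif(50, 0.05, 0.15))
  ld <- toy_ld(R)
  cn <- to_canonical(st, ld)
  pr <- structure(list(pi = rep(0.1, 50), sigma_beta2 = 0.02, theta0 = NA,
                       theta = NA, h = NA), class = "prior_spec")
  fa <- vb_fit(cn, pr, tol = 1e-10, max_iter = 2000, accelerate = TRUE, seed = 7)
  fp <- vb_fit(cn, pr, tol = 1e-10, max_iter = 2000, accelerate = FALSE, seed = 7)
  expect_equal(fa$alpha, fp$alpha, tolerance = 1e-6)
  expect_equal(fa$mu, fp$mu, tolerance = 1e-6)
  expect_equal(fa$lower_bound, fp$lower_bound, tolerance = 1e-6)
})

test_that("fits are deterministic under a fixed seed", {
  R <- rand_pd_corr(15, seed = 8)
  st <- toy_stats(rnorm(15, 0, 0.05), runif(15, 0.05, 0.2))
  cn <- to_canonical(st, toy_ld(R))
  pr <- structure(list(pi = rep(0.15, 15), sigma_beta2 = 0.03, theta0 = NA,
                       theta = NA, h = NA), class = "prior_spec")
  f1 <- vb_fit(cn, pr, seed = 99)
  f2 <- vb_fit(cn, pr, seed = 99)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$lower_bound, f2$lower_bound)
})

test_that("enumeration oracle: pi = 1 reduces to a single Gaussian marginal", {
  R <- rand_pd_corr(4, seed = 5)
  st <- toy_stats(c(0.1, 0, -0.2, 0.05), rep(0.1, 4))
  sb2 <- 0.03
  S <- diag(st$se)
  A <- S %*% R %*% diag(1 / st$se)
  Sig <- S %*% R %*% S + sb2 * A %*% t(A)
  direct <- -0.5 * (4 * log(2 * pi) + determinant(Sig)$modulus[1] +
                      t(st$betahat) %*% solve(Sig, st$betahat))
  expect_equal(exact_log_marginal_oracle(st, toy_ld(R), rep(1 - 1e-14, 4), sb2),
               as.numeric(direct), tolerance = 1e-8)
  expect_error(exact_log_marginal_oracle(toy_stats(rnorm(16), rep(0.1, 16)),
                                         toy_ld(diag(16)), rep(0.5, 16), 0.01),
               "p <= 15")
})

test_that("variational lower bound never exceeds the enumeration oracle", {
  set.seed(12)
  for (rep in 1:30) {
    p <- sample(2:10, 1)
    R <- rand_pd_corr(p, seed = rep + 100)
    st <- toy_stats(rnorm(p, 0, 0.08), runif(p, 0.05, 0.15))
    ld <- toy_ld(R)
    cn <- to_canonical(st, ld)
    pi <- runif(p, 0.02, 0.5)
    sb2 <- runif(1, 0.002, 0.05)
    pr <- structure(list(pi = pi, sigma_beta2 = sb2, theta0 = NA, theta = NA,
                         h = NA), class = "prior_spec")
    f <- vb_fit(cn, pr, tol = 1e-8, max_iter = 1000, seed = rep)
    orc <- exact_log_marginal_oracle(st, ld, pi, sb2)
    expect_lte(f$lower_bound, orc + 1e-6)
    expect_true(is.finite(orc))
  }
})
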