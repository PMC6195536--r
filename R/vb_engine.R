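#' Canonical form of the summary-statistic likelihood
#'
#' The multivariate-normal likelihood relating the observed single-SNP
#' estimates to the true multi-SNP effects,
#' \deqn{\hat\beta \sim N(\hat S \hat R \hat S^{-1} \beta,\; \hat S \hat R \hat S),}
#' is an exponential family in \eqn{\beta}:
#' \eqn{\log p(\hat\beta \mid \beta) = \mathrm{const} + \beta' q - \tfrac12 \beta' H \beta}
#' with \eqn{q = \hat S^{-2}\hat\beta} and \eqn{H = \hat S^{-1}\hat R\hat S^{-1}}.
#' `H` inherits the banded block structure of the LD estimate, and the
#' constant (the log-density at \eqn{\beta = 0}) is evaluated once per block
#' through a banded Cholesky factorization.
#'
#' @param stats Summary-statistic table (see [read_summary_stats()]); rows
#'   must align one-to-one with the SNPs of `ld`.
#' @param ld A `banded_ld` object from [estimate_shrunk_ld()].
#' @return An object of class `rss_canonical` holding `q`, the banded blocks
#'   of `H`, and the per-block log-normalizing constants.
#' @export
to_canonical <- function(stats, ld) {
  stopifnot(inherits(ld, "banded_ld"))
  p <- nrow(stats)
  if (p != ld$p) stop("summary stats (", p, " SNPs) and LD (", ld$p,
                      " SNPs) do not align")
  if (!is.null(ld$snp$pos) && !is.null(stats$pos) &&
      !all(ld$snp$pos == stats$pos))
    stop("summary stats and LD panel positions differ; harmonize inputs first")
  se <- stats$se
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be positive")
  betahat <- stats$betahat
  q <- betahat / se^2
  blocks <- vector("list", length(ld$blocks))
  logn0 <- 0
  for (b in seq_along(ld$blocks)) {
    blk <- ld$blocks[[b]]
    idx <- blk$idx; m <- length(idx); bw <- blk$bw
    seb <- se[idx]
    Hband <- blk$band
    Sband <- blk$band
    Hband[1L, ] <- 1 / seb^2
    Sband[1L, ] <- seb^2
    for (k in seq_len(bw)) {
      j <- seq_len(m - k)
      Hband[k + 1L, j] <- blk$band[k + 1L, j] / (seb[j] * seb[j + k])
      Sband[k + 1L, j] <- blk$band[k + 1L, j] * (seb[j] * seb[j + k])
    }
    ch <- .band_chol(Sband)
    if (!isTRUE(ch$ok))
      stop("likelihood covariance of block ", b, " is not positive-definite")
    bb <- betahat[idx]
    quad <- sum(bb * .band_chol_solve(ch$L, bb))
    ln0 <- -0.5 * (m * log(2 * pi) + ch$logdet + quad)
    blocks[[b]] <- list(idx = idx, Hband = Hband, bw = bw, logn0 = ln0)
    logn0 <- logn0 + ln0
  }
  structure(list(q = q, betahat = betahat, se = se,
                 n = stats$n %||% rep(NA_real_, p),
                 blocks = blocks, logn0 = logn0, p = p,
                 snp = stats[, intersect(c("snp_id", "chrom", "pos"),
                                         names(stats)), drop = FALSE]),
            class = "rss_canonical")
}

#' Bundle the spike-and-slab prior for one hyperparameter point
#'
#' Combines the background/enrichment log10-odds and the
#' approximate-heritability parameter into the per-SNP prior inclusion
#' probabilities and the slab variance used by the variational fit.
#'
#' @param theta0,theta,h Hyperparameters (see [prior_inclusion_probs()] and
#'   [slab_variance()]).
#' @param annotation A `snp_annotation` (or binary vector), or `NULL` for no
#'   annotation (all SNPs outside).
#' @param stats Summary-statistic table (or an `rss_canonical`) supplying
#'   `se` and `n`.
#' @return Object of class `prior_spec` with elements `theta0`, `theta`,
#'   `h`, `pi`, `sigma_beta2`.
#' @export
prior_spec <- function(theta0, theta, h, annotation = NULL, stats) {
  a <- if (is.null(annotation)) rep(0, length(stats$se)) else annotation_vector(annotation)
  pi <- prior_inclusion_probs(theta0, theta, a)
  sb2 <- slab_variance(h, pi, stats$n, stats$se)
  structure(list(theta0 = theta0, theta = theta, h = h, pi = pi,
                 sigma_beta2 = sb2),
            class = "prior_spec")
}

annotation_vector <- function(annotation) {
  if (inherits(annotation, "snp_annotation")) annotation$a else as.numeric(annotation)
}

# Evidence lower bound for one block given current variational parameters.
block_lower_bound <- function(alpha, mu, q, Hband, logodds, sigma_beta2, logn0) {
  eps <- 1e-12
  alpha <- pmin(pmax(alpha, eps), 1 - eps)
  Hjj <- Hband[1L, ]
  s2 <- sigma_beta2 / (sigma_beta2 * Hjj + 1)
  elik <- .vb_elik(q, Hband, alpha, mu, sigma_beta2)
  pi <- 1 / (1 + exp(-logodds))
  kl_bin <- sum(alpha * (log(alpha) - log(pi)) +
                (1 - alpha) * (log1p(-alpha) - log1p(-pi)))
  kl_norm <- sum(alpha * 0.5 * (log(sigma_beta2 / s2) +
                                (s2 + mu^2) / sigma_beta2 - 1))
  logn0 + elik - kl_bin - kl_norm
}

vb_fit_block <- function(q, Hband, logodds, sigma_beta2, alpha, mu, upd,
                         tol, max_iter, accelerate, logn0) {
  m <- length(q)
  eps <- 1e-12
  alpha <- pmin(pmax(alpha, eps), 1 - eps)
  Hr <- .band_sym_mv(Hband, alpha * mu)
  fwd <- seq_len(m); bwd <- rev(fwd)
  bound <- block_lower_bound(alpha, mu, q, Hband, logodds, sigma_beta2, logn0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a0 <- alpha; m0 <- mu; r0 <- a0 * m0
    s1 <- .vb_pass(q, Hband, alpha, mu, Hr, logodds, sigma_beta2, fwd, upd)
    s2 <- .vb_pass(q, Hband, s1$alpha, s1$mu, s1$Hr, logodds, sigma_beta2, bwd, upd)
    alpha <- s2$alpha; mu <- s2$mu; Hr <- s2$Hr
    bound <- block_lower_bound(alpha, mu, q, Hband, logodds, sigma_beta2, logn0)
    if (accelerate) {
      ra <- s1$alpha - a0; rm <- s1$mu - m0
      va <- s2$alpha - 2 * s1$alpha + a0; vm <- s2$mu - 2 * s1$mu + m0
      sv <- sum(va^2) + sum(vm^2)
      if (sv > 0) {
        step <- -sqrt((sum(ra^2) + sum(rm^2)) / sv)
        if (step > -1) step <- -1
        ax <- pmin(pmax(a0 - 2 * step * ra + step^2 * va, eps), 1 - eps)
        mx <- m0 - 2 * step * rm + step^2 * vm
        Hx <- .band_sym_mv(Hband, ax * mx)
        sx <- .vb_pass(q, Hband, ax, mx, Hx, logodds, sigma_beta2, fwd, upd)
        bx <- block_lower_bound(sx$alpha, sx$mu, q, Hband, logodds,
                                sigma_beta2, logn0)
        if (is.finite(bx) && bx >= bound) {   # reject steps that lower the bound
          alpha <- sx$alpha; mu <- sx$mu; Hr <- sx$Hr; bound <- bx
        }
      }
    }
    if (max(abs(alpha - a0)) < tol && max(abs(alpha * mu - r0)) < tol) {
      converged <- TRUE
      break
    }
  }
  Hjj <- Hband[1L, ]
  list(alpha = alpha, mu = mu,
       s2 = sigma_beta2 / (sigma_beta2 * Hjj + 1),
       bound = bound, n_iter = it, converged = converged)
}

#' Variational fit of the spike-and-slab posterior for one hyperparameter point
#'
#' Coordinate-ascent variational inference under the fully factorized
#' spike-and-slab family, with forward/backward alternating update order and
#' a safeguarded squared-extrapolation (SQUAREM-style) acceleration: any
#' extrapolated step that would lower the evidence lower bound falls back to
#' the plain coordinate update.  Blocks of the banded likelihood are fitted
#' independently and their bounds summed.
#'
#' @param canon Canonical likelihood from [to_canonical()].
#' @param prior A `prior_spec` from [prior_spec()].
#' @param init Optional list with `alpha` and `mu` start vectors (length p);
#'   defaults to a seeded random initialization, see [vb_random_init()].
#' @param tol Convergence tolerance on `max |change in alpha|` and
#'   `max |change in alpha*mu|` between outer iterations (default 1e-4).
#' @param max_iter Maximum outer iterations (each is two coordinate passes,
#'   default 200); reaching it returns `converged = FALSE` with a warning.
#' @param accelerate Use the safeguarded extrapolation (default `TRUE`).
#' @param update_only Optional logical/index vector restricting which SNPs
#'   are updated (others keep their initial variational parameters); used by
#'   the enrichment-reuse computation.
#' @param seed Seed for the default random initialization (default 42).
#' @return Object of class `vb_fit`: posterior inclusion probabilities
#'   `alpha`, conditional means `mu` and variances `s2`, the evidence
#'   `lower_bound`, iteration count and convergence flag.
#' @export
vb_fit <- function(canon, prior, init = NULL, tol = 1e-4, max_iter = 200,
                   accelerate = TRUE, update_only = NULL, seed = 42) {
  stopifnot(inherits(canon, "rss_canonical"), inherits(prior, "prior_spec"))
  p <- canon$p
  if (is.null(init)) init <- vb_random_init(p, sqrt(prior$sigma_beta2), seed)
  stopifnot(length(init$alpha) == p, length(init$mu) == p)
  upd <- rep(TRUE, p)
  if (!is.null(update_only)) {
    upd <- rep(FALSE, p)
    upd[update_only] <- TRUE
  }
  logodds <- log(prior$pi) - log1p(-prior$pi)
  alpha <- numeric(p); mu <- numeric(p); s2 <- numeric(p)
  bound <- 0; n_iter <- 0L; conv <- TRUE
  for (blk in canon$blocks) {
    idx <- blk$idx
    fb <- vb_fit_block(canon$q[idx], blk$Hband, logodds[idx],
                       prior$sigma_beta2, init$alpha[idx], init$mu[idx],
                       upd[idx], tol, max_iter, accelerate, blk$logn0)
    alpha[idx] <- fb$alpha; mu[idx] <- fb$mu; s2[idx] <- fb$s2
    bound <- bound + fb$bound
    n_iter <- max(n_iter, fb$n_iter)
    conv <- conv && fb$converged
  }
  if (!conv) warning("variational fit did not converge in ", max_iter,
                     " iterations")
  structure(list(alpha = alpha, mu = mu, s2 = s2, lower_bound = bound,
                 n_iter = n_iter, converged = conv,
                 sigma_beta2 = prior$sigma_beta2,
                 theta0 = prior$theta0, theta = prior$theta, h = prior$h),
            class = "vb_fit")
}

#' One coordinate pass of the variational updates
#'
#' Updates each SNP once in the given order: the conditional variance
#' \eqn{s_j^2 = \sigma_\beta^2/(\sigma_\beta^2 H_{jj} + 1)}, the conditional
#' mean \eqn{\mu_j = s_j^2 (q_j - \sum_{k \ne j} H_{jk}\alpha_k\mu_k)}, and
#' the inclusion log-odds
#' \eqn{\mathrm{logit}\,\alpha_j = \mathrm{logit}\,\pi_j + \tfrac12\log(s_j^2/\sigma_\beta^2) + \mu_j^2/(2 s_j^2)}.
#' Mostly useful for inspection and tests; [vb_fit()] runs these passes to
#' convergence.
#'
#' @param fit A `vb_fit` (or list with `alpha` and `mu`).
#' @inheritParams vb_fit
#' @param order `"forward"` or `"backward"`.
#' @return The updated fit (class `vb_fit`) with its recomputed lower bound.
#' @export
vb_coordinate_pass <- function(fit, canon, prior, order = c("forward", "backward")) {
  order <- match.arg(order)
  p <- canon$p
  logodds <- log(prior$pi) - log1p(-prior$pi)
  alpha <- pmin(pmax(fit$alpha, 1e-12), 1 - 1e-12)
  mu <- fit$mu
  bound <- 0
  for (blk in canon$blocks) {
    idx <- blk$idx
    m <- length(idx)
    ord <- if (order == "forward") seq_len(m) else rev(seq_len(m))
    Hr <- .band_sym_mv(blk$Hband, alpha[idx] * mu[idx])
    st <- .vb_pass(canon$q[idx], blk$Hband, alpha[idx], mu[idx], Hr,
                   logodds[idx], prior$sigma_beta2, ord, rep(TRUE, m))
    alpha[idx] <- st$alpha; mu[idx] <- st$mu
    bound <- bound + block_lower_bound(st$alpha, st$mu, canon$q[idx],
                                       blk$Hband, logodds[idx],
                                       prior$sigma_beta2, blk$logn0)
  }
  s2 <- numeric(p)
  for (blk in canon$blocks) s2[blk$idx] <- prior$sigma_beta2 /
      (prior$sigma_beta2 * blk$Hband[1L, ] + 1)
  structure(list(alpha = alpha, mu = mu, s2 = s2, lower_bound = bound,
                 n_iter = 1L, converged = FALSE,
                 sigma_beta2 = prior$sigma_beta2,
                 theta0 = prior$theta0, theta = prior$theta, h = prior$h),
            class = "vb_fit")
}

#' Evidence lower bound of a variational fit
#'
#' Closed-form bound
#' \eqn{E_q[\log p(\hat\beta\mid\beta)] - KL(q \,\|\, \mathrm{prior})}
#' under the factorized spike-and-slab family; never exceeds the exact log
#' marginal likelihood.
#'
#' @inheritParams vb_coordinate_pass
#' @return Scalar lower bound.
#' @export
variational_lower_bound <- function(fit, canon, prior) {
  logodds <- log(prior$pi) - log1p(-prior$pi)
  bound <- 0
  for (blk in canon$blocks) {
    idx <- blk$idx
    bound <- bound + block_lower_bound(fit$alpha[idx], fit$mu[idx],
                                       canon$q[idx], blk$Hband, logodds[idx],
                                       prior$sigma_beta2, blk$logn0)
  }
  bound
}

#' Seeded random initialization for the variational parameters
#'
#' Draws `alpha_j ~ Uniform(0,1)` and `mu_j ~ Normal(0, sigma_beta)`.  The
#' grid-fitting functions draw one such initialization and reuse it (with
#' `mu` rescaled to each grid point's slab standard deviation) across the
#' whole hyperparameter grid.
#'
#' @param p Number of SNPs.
#' @param sigma_beta Slab standard deviation used to scale `mu`.
#' @param seed Integer seed.
#' @return List with `alpha` and `mu`.
#' @export
vb_random_init <- function(p, sigma_beta, seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  list(alpha = runif(p), mu = rnorm(p, 0, sigma_beta))
}

#' Exact log marginal likelihood by enumeration (test oracle)
#'
#' Sums, over all \eqn{2^p} inclusion patterns \eqn{\gamma}, the pattern's
#' prior probability times the Gaussian marginal density
#' \eqn{N(\hat\beta;\, 0,\; \hat S\hat R\hat S + \sigma_\beta^2 A_{\cdot\gamma} A_{\cdot\gamma}')}
#' with \eqn{A = \hat S \hat R \hat S^{-1}}, accumulated in log space.
#' Exponential in `p`; guarded at `p <= 15`.  Serves as the independent
#' reference the variational lower bound is checked against.
#'
#' @param stats Summary-statistic table (uses `betahat` and `se`).
#' @param ld A `banded_ld` object (expanded densely).
#' @param pi Vector of prior inclusion probabilities.
#' @param sigma_beta2 Slab variance.
#' @return Exact log marginal likelihood (natural log).
#' @export
exact_log_marginal_oracle <- function(stats, ld, pi, sigma_beta2) {
  p <- nrow(stats)
  if (p > 15) stop("enumeration oracle is limited to p <= 15 (got ", p, ")")
  stopifnot(length(pi) == p, all(pi >= 0), all(pi <= 1))
  R <- matrix(0, p, p)
  for (blk in ld$blocks) R[blk$idx, blk$idx] <- band_to_dense(blk$band)
  se <- stats$se; bhat <- stats$betahat
  SRS <- R * outer(se, se)
  A <- R * outer(se, 1 / se)          # S R S^{-1}
  log_pi <- log(pi); log_1mpi <- log1p(-pi)
  terms <- numeric(2^p)
  for (g in 0:(2^p - 1)) {
    gam <- as.logical(bitwAnd(g, bitwShiftL(1L, 0:(p - 1L))))
    Sig <- SRS
    if (any(gam)) {
      Ag <- A[, gam, drop = FALSE]
      Sig <- Sig + sigma_beta2 * tcrossprod(Ag)
    }
    ch <- chol(Sig)
    quad <- sum(backsolve(ch, bhat, transpose = TRUE)^2)
    logdens <- -0.5 * (p * log(2 * base::pi) + 2 * sum(log(diag(ch))) + quad)
    terms[g + 1L] <- sum(log_pi[gam]) + sum(log_1mpi[!gam]) + logdens
  }
  logsumexp(terms)
}

#' @export
print.vb_fit <- function(x, ...) {
  cat("Variational fit: ", length(x$alpha), " SNPs, lower bound ",
      format(x$lower_bound, digits = 8), ", ", x$n_iter, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}
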