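#' Fit the baseline model over the hyperparameter grid
#'
#' Runs one variational fit per `(theta0, h)` grid point with the enrichment
#' parameter fixed at 0.  A single random initialization (see
#' [vb_random_init()]) is drawn once and reused for every grid point, with
#' the `mu` component rescaled to each point's slab standard deviation.
#' Posterior grid weights are proportional to `exp(lower bound)` under the
#' uniform grid prior, normalized by log-sum-exp.
#'
#' @param canon Canonical likelihood from [to_canonical()].
#' @param grid A baseline `hyper_grid` (all `theta = 0`), e.g.
#'   `default_grids("baseline")`.
#' @param seed Seed for the shared random initialization (default 42).
#' @param tol,max_iter,accelerate Passed to [vb_fit()].
#' @return Object of class `grid_fits`: per-point `fits`, the `grid`,
#'   `bounds`, normalized `weights`, and the shared initialization.
#' @export
fit_baseline_grid <- function(canon, grid, seed = 42, tol = 1e-4,
                              max_iter = 200, accelerate = TRUE) {
  stopifnot(inherits(grid, "hyper_grid"))
  if (any(grid$theta != 0))
    stop("baseline grid must have theta = 0 at every point")
  init_raw <- vb_random_init(canon$p, 1, seed)
  fits <- vector("list", nrow(grid))
  bounds <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pr <- prior_spec(grid$theta0[g], 0, grid$h[g], NULL, canon)
    init <- list(alpha = init_raw$alpha,
                 mu = init_raw$mu * sqrt(pr$sigma_beta2))
    f <- vb_fit(canon, pr, init = init, tol = tol, max_iter = max_iter,
                accelerate = accelerate)
    if (!is.finite(f$lower_bound))
      stop("non-finite lower bound at grid point theta0=", grid$theta0[g],
           ", h=", grid$h[g])
    fits[[g]] <- f
    bounds[g] <- f$lower_bound
  }
  structure(list(fits = fits, grid = grid, bounds = bounds,
                 weights = softmax_weights(bounds), seed = seed,
                 init_raw = init_raw, model = "M0"),
            class = "grid_fits")
}

softmax_weights <- function(bounds) {
  w <- exp(bounds - max(bounds))
  w / sum(w)
}

# inside-set SNPs plus anything sharing a band with them
reuse_update_mask <- function(canon, annotation) {
  a <- annotation_vector(annotation)
  upd <- logical(canon$p)
  for (blk in canon$blocks) {
    m <- length(blk$idx)
    inb <- which(a[blk$idx] == 1)
    loc <- logical(m)
    for (i in inb) loc[max(1L, i - blk$bw):min(m, i + blk$bw)] <- TRUE
    upd[blk$idx] <- loc
  }
  which(upd)
}

#' Fit the enrichment model over the grid, reusing the baseline fits
#'
#' For each `(theta0, theta > 0, h)` point, the variational parameters are
#' initialized from the baseline fit at the matching `(theta0, h)` and, by
#' default, only SNPs inside the annotated set plus SNPs sharing an LD band
#' with them are updated, all others staying at their baseline values.
#' This reuse of the genome-wide baseline computation is what makes
#' scanning thousands of gene sets affordable; `reuse = FALSE` refits all
#' SNPs for validation.
#'
#' @inheritParams fit_baseline_grid
#' @param grid An enrichment `hyper_grid` (all `theta > 0`).
#' @param annotation `snp_annotation` of the tested set (must be non-empty).
#' @param baseline_fits `grid_fits` from [fit_baseline_grid()] covering
#'   every `(theta0, h)` of `grid`.
#' @param reuse Restrict updates to inside-set and band-neighbor SNPs
#'   (default `TRUE`).
#' @return A `grid_fits` for the enrichment model.
#' @export
fit_enrichment_grid <- function(canon, grid, annotation, baseline_fits,
                                reuse = TRUE, tol = 1e-4, max_iter = 200,
                                accelerate = TRUE) {
  stopifnot(inherits(grid, "hyper_grid"), inherits(baseline_fits, "grid_fits"))
  a <- annotation_vector(annotation)
  if (sum(a) == 0) stop("annotation is empty: no SNP inside the set")
  g0 <- baseline_fits$grid
  base_idx <- match(paste(grid$theta0, grid$h), paste(g0$theta0, g0$h))
  if (anyNA(base_idx))
    stop("baseline fits lack (theta0, h) points required by the enrichment grid")
  upd <- if (reuse) reuse_update_mask(canon, annotation) else NULL
  fits <- vector("list", nrow(grid))
  bounds <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    bf <- baseline_fits$fits[[base_idx[g]]]
    if (grid$theta[g] == 0) {          # same prior as baseline: reuse as-is
      fits[[g]] <- bf
      bounds[g] <- bf$lower_bound
      next
    }
    pr <- prior_spec(grid$theta0[g], grid$theta[g], grid$h[g], a, canon)
    f <- vb_fit(canon, pr, init = list(alpha = bf$alpha, mu = bf$mu),
                tol = tol, max_iter = max_iter, accelerate = accelerate,
                update_only = upd)
    if (!is.finite(f$lower_bound))
      stop("non-finite lower bound at grid point theta0=", grid$theta0[g],
           ", theta=", grid$theta[g], ", h=", grid$h[g])
    fits[[g]] <- f
    bounds[g] <- f$lower_bound
  }
  structure(list(fits = fits, grid = grid, bounds = bounds,
                 weights = softmax_weights(bounds), seed = baseline_fits$seed,
                 model = "M1",
                 annotation_name = if (inherits(annotation, "snp_annotation"))
                   annotation$set_name else "annotation"),
            class = "grid_fits")
}

#' Enrichment Bayes factor on the log10 scale
#'
#' Averages the per-grid-point evidence under uniform grid priors:
#' \deqn{\log_{10} \mathrm{BF} = \log_{10}\overline{\exp(\mathrm{bound}_g)}_{g \in M_1}
#'   - \log_{10}\overline{\exp(\mathrm{bound}_g)}_{g \in M_0},}
#' computed by log-sum-exp.  The observed summary data are BF times more
#' likely under the enrichment model than under the baseline model.
#'
#' @param baseline,enrichment `grid_fits` objects (or bare numeric vectors
#'   of per-point lower bounds).
#' @return Scalar log10 Bayes factor.
#' @export
log10_bf <- function(baseline, enrichment) {
  b0 <- if (inherits(baseline, "grid_fits")) baseline$bounds else as.numeric(baseline)
  b1 <- if (inherits(enrichment, "grid_fits")) enrichment$bounds else as.numeric(enrichment)
  stopifnot(length(b0) >= 1, length(b1) >= 1)
  ((logsumexp(b1) - log(length(b1))) - (logsumexp(b0) - log(length(b0)))) / log(10)
}

weighted_ci <- function(values, weights, level = 0.95) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w) / sum(w)
  lo <- v[which(cw >= (1 - level) / 2)[1]]
  hi <- v[which(cw >= 1 - (1 - level) / 2)[1]]
  c(lo, hi)
}

#' Posterior distribution of the hyperparameters on the grid
#'
#' Normalizes `exp(lower bound)` over the grid (uniform prior) and reports
#' the posterior mean and central 95% credible interval of each
#' hyperparameter by weighted quantiles on the grid values.
#'
#' @param fits A `grid_fits` object, or a numeric vector of bounds.
#' @param grid The matching `hyper_grid` (taken from `fits` if omitted).
#' @return List with `table` (grid plus posterior `weight`) and `summary`
#'   (one row per hyperparameter: mean, lower, upper).
#' @export
hyperparam_posterior <- function(fits, grid = NULL) {
  if (inherits(fits, "grid_fits")) {
    grid <- grid %||% fits$grid
    bounds <- fits$bounds
  } else bounds <- as.numeric(fits)
  stopifnot(nrow(grid) == length(bounds))
  w <- softmax_weights(bounds)
  tab <- grid
  tab$weight <- w
  params <- c("theta0", "theta", "h")
  summ <- do.call(rbind, lapply(params, function(pn) {
    ci <- weighted_ci(grid[[pn]], w)
    data.frame(param = pn, mean = sum(w * grid[[pn]]),
               lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ)
}

#' Full enrichment test of one SNP annotation
#'
#' Convenience wrapper: fits (or takes) the baseline grid, fits the
#' enrichment grid with baseline reuse, and assembles the Bayes factor and
#' hyperparameter posteriors into a single result.
#'
#' @inheritParams fit_enrichment_grid
#' @param grid0,grid1 Baseline and enrichment grids (defaults
#'   [default_grids()]); `grid1`'s `(theta0, h)` values must occur in
#'   `grid0`.
#' @param baseline_fits Optional precomputed [fit_baseline_grid()] result
#'   (reused across many gene sets).
#' @param seed Seed for the shared initialization when the baseline is fit
#'   here.
#' @return Object of class `enrichment_result`: `name`, `log10_bf`,
#'   `theta_mean`, `theta_ci`, the two grid posteriors, per-point bounds
#'   and `n_inside_snps`.
#' @export
test_enrichment <- function(canon, annotation, grid0 = default_grids("baseline"),
                            grid1 = default_grids("enrichment"),
                            baseline_fits = NULL, reuse = TRUE, seed = 42,
                            tol = 1e-4, max_iter = 200) {
  if (is.null(baseline_fits))
    baseline_fits <- fit_baseline_grid(canon, grid0, seed = seed, tol = tol,
                                       max_iter = max_iter)
  enr <- fit_enrichment_grid(canon, grid1, annotation, baseline_fits,
                             reuse = reuse, tol = tol, max_iter = max_iter)
  post1 <- hyperparam_posterior(enr)
  post0 <- hyperparam_posterior(baseline_fits)
  th <- post1$summary[post1$summary$param == "theta", ]
  structure(list(
    name = if (inherits(annotation, "snp_annotation")) annotation$set_name
           else "annotation",
    log10_bf = log10_bf(baseline_fits, enr),
    theta_mean = th$mean, theta_ci = c(th$lower, th$upper),
    posterior_m0 = post0, posterior_m1 = post1,
    bounds_m0 = baseline_fits$bounds, bounds_m1 = enr$bounds,
    n_inside_snps = sum(annotation_vector(annotation)),
    baseline = baseline_fits, enrichment = enr, flags = list()),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment result '", x$name, "': log10 BF = ",
      format(x$log10_bf, digits = 4), "; theta posterior mean ",
      format(x$theta_mean, digits = 3), " [",
      format(x$theta_ci[1], digits = 3), ", ",
      format(x$theta_ci[2], digits = 3), "]; ",
      x$n_inside_snps, " inside SNPs\n", sep = "")
  invisible(x)
}

mixture_z_loglik <- function(par, z) {
  p1 <- stats::plogis(par[1])
  sd1 <- sqrt(1 + exp(par[2]))
  sum(log((1 - p1) * dnorm(z) + p1 * dnorm(z, 0, sd1)))
}

fit_mixture_z <- function(z, start = c(qlogis(0.05), log(4))) {
  opt <- optim(start, mixture_z_loglik, z = z, method = "BFGS",
               control = list(fnscale = -1, maxit = 500))
  ll0 <- mixture_z_loglik(start, z)
  if (opt$value < ll0) { opt$par <- start; opt$value <- ll0 }
  list(pi = stats::plogis(opt$par[1]), sigma2 = exp(opt$par[2]),
       loglik = opt$value, par = opt$par)
}

#' Likelihood-ratio sanity check on inside vs outside z-scores
#'
#' Fits the two-component scale mixture
#' `z ~ (1-pi) N(0,1) + pi N(0, 1+sigma^2)` to the inside-set and
#' outside-set z-scores separately and with shared parameters, and returns
#' the likelihood-ratio statistic
#' `LR = 2 [ (ll_inside + ll_outside at separate MLEs) - (joint ll at the shared MLE) ] >= 0`.
#' Also returns kernel-density summaries of both groups for the visual
#' check.  This statistic ignores LD, so it complements rather than
#' replaces the Bayes factor: a large BF with a near-zero LR (or inside
#' densities indistinguishable from outside) warns that the model-based
#' enrichment may be driven by model misspecification rather than signal.
#'
#' @param z_inside,z_outside Numeric vectors of z-scores
#'   (`betahat / se`), both non-empty; groups smaller than 10 give a
#'   warning but still return the statistic.
#' @return List with `lr`, the fitted mixtures (`fit_inside`,
#'   `fit_outside`, `fit_pooled`) and density summaries (`dens_inside`,
#'   `dens_outside`).
#' @export
zscore_lr_check <- function(z_inside, z_outside) {
  stopifnot(length(z_inside) >= 1, length(z_outside) >= 1)
  if (length(z_inside) < 10 || length(z_outside) < 10)
    warning("fewer than 10 z-scores in a group; LR statistic is unstable")
  pooled_ll <- function(par) mixture_z_loglik(par, z_inside) +
    mixture_z_loglik(par, z_outside)
  optp <- optim(c(qlogis(0.05), log(4)), pooled_ll, method = "BFGS",
                control = list(fnscale = -1, maxit = 500))
  fit_in <- fit_mixture_z(z_inside, start = optp$par)
  fit_out <- fit_mixture_z(z_outside, start = optp$par)
  lr <- 2 * (fit_in$loglik + fit_out$loglik - optp$value)
  lr <- max(lr, 0)
  list(lr = lr,
       fit_inside = fit_in[c("pi", "sigma2", "loglik")],
       fit_outside = fit_out[c("pi", "sigma2", "loglik")],
       fit_pooled = list(pi = stats::plogis(optp$par[1]),
                         sigma2 = exp(optp$par[2]), loglik = optp$value),
       dens_inside = density(z_inside), dens_outside = density(z_outside))
}

#' Sanity suite for one enrichment result
#'
#' Three checks guard against spurious enrichment: (i) the set's Bayes
#' factor is compared with the BF of the all-genes annotation (a set whose
#' BF does not exceed generic genic enrichment is flagged
#' `"generic-genic"`); (ii) it is compared with the 95th percentile of BFs
#' of `k` random size-matched near-gene null sets; (iii) the inside/outside
#' z-score likelihood-ratio check is attached.  Deterministic under a fixed
#' `seed`.
#'
#' @param result An `enrichment_result` from [test_enrichment()].
#' @param canon Canonical likelihood the result was fitted on.
#' @param annotation The tested `snp_annotation`.
#' @param genes Gene annotation table (for the all-genes comparator).
#' @param stats Summary-statistic table (positions and z-scores).
#' @param seed Seed for the null-set draws (default 1).
#' @param k Number of null sets (default 20).
#' @return The result with `flags` filled in: each of `generic_genic` and
#'   `null_sets` is `"pass"` or `"warn"`, plus the comparator values and
#'   the LR check.
#' @export
run_sanity_suite <- function(result, canon, annotation, genes, stats,
                             seed = 1, k = 20) {
  stopifnot(inherits(result, "enrichment_result"))
  universe <- all_genes_annotation(genes, stats, annotation$window)
  grid1 <- result$enrichment$grid
  bf_all <- log10_bf(result$baseline,
                     fit_enrichment_grid(canon, grid1, universe,
                                         result$baseline))
  null_bfs <- vapply(seq_len(k), function(i) {
    nul <- random_matched_null_set(universe, annotation$n_inside,
                                   seed = seed + i)
    log10_bf(result$baseline,
             fit_enrichment_grid(canon, grid1, nul, result$baseline))
  }, 0)
  z <- stats$betahat / stats$se
  a <- annotation_vector(annotation)
  lr <- zscore_lr_check(z[a == 1], z[a == 0])
  result$flags <- list(
    generic_genic = if (result$log10_bf >= bf_all) "pass" else "warn",
    null_sets = if (result$log10_bf > quantile(null_bfs, 0.95)) "pass" else "warn",
    bf_all_genes = bf_all, null_bfs = null_bfs, lr_check = lr)
  result
}
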