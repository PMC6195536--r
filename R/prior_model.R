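#' Per-SNP prior inclusion probabilities under the enrichment prior
#'
#' Each SNP is trait-associated a priori with probability
#' \deqn{\pi_j = (1 + 10^{-(\theta_0 + a_j \theta)})^{-1},}
#' where `theta0` is the background log10-odds of association, `theta` the
#' additional log10-odds for SNPs inside the annotated set, and `a` the 0/1
#' annotation vector.  With `theta = 2` the prior odds of association are
#' 100-fold higher inside the set than outside.
#'
#' @param theta0 Background log10-odds of a SNP being trait-associated
#'   (typically negative, e.g. -3 means about 1 in 1000 SNPs).
#' @param theta Enrichment parameter (log10-odds increase inside the set),
#'   `>= 0`; 0 recovers the baseline (no-enrichment) model.
#' @param a Binary annotation vector (1 = inside the SNP set).
#' @return Numeric vector of prior inclusion probabilities, strictly in (0,1).
#' @export
prior_inclusion_probs <- function(theta0, theta, a) {
  stopifnot(length(theta0) == 1L, length(theta) == 1L, is.finite(theta0),
            is.finite(theta))
  a <- as.numeric(a)
  if (!all(a %in% c(0, 1))) stop("annotation vector `a` must be binary (0/1)")
  1 / (1 + 10^(-(theta0 + a * theta)))
}

#' Slab variance implied by the approximate heritability parameter
#'
#' Converts the hyperparameter `h` (the approximate proportion of phenotypic
#' variance explained by all SNPs jointly) into the prior effect-size
#' variance of trait-associated SNPs:
#' \deqn{\sigma_\beta^2 = h \cdot \left(\sum_j \pi_j n_j^{-1} \hat s_j^{-2}\right)^{-1}.}
#' The term \eqn{n^{-1}\hat s_j^{-2}} approximates the genotype variance of
#' SNP j in phenotypic-variance units, so the sum is the expected total
#' variance contributed per unit of \eqn{\sigma_\beta^2}.
#'
#' @param h Approximate proportion of phenotypic variance explained, in
#'   `[0, 1)`.
#' @param pi Vector of prior inclusion probabilities (from
#'   [prior_inclusion_probs()]).
#' @param n GWAS sample size; scalar or per-SNP vector.
#' @param se Vector of single-SNP standard errors, all positive.
#' @return The scalar slab variance \eqn{\sigma_\beta^2}.
#' @export
slab_variance <- function(h, pi, n, se) {
  stopifnot(length(h) == 1L, h >= 0, h < 1, all(se > 0), all(n > 0))
  if (length(n) == 1L) n <- rep(n, length(se))
  stopifnot(length(pi) == length(se), length(n) == length(se))
  denom <- sum(pi / (n * se^2))
  if (denom <= 0) stop("sum of pi_j / (n_j * se_j^2) must be positive")
  h / denom
}

#' Construct a hyperparameter grid
#'
#' The model is fitted over a discrete grid of hyperparameter triples
#' `(theta0, theta, h)` with a uniform prior weight on each point.  The
#' baseline model M0 is the grid restricted to `theta = 0`; the enrichment
#' model M1 uses `theta > 0`.
#'
#' @param theta0 Numeric vector of background log10-odds values.
#' @param theta Numeric vector of enrichment values (all 0 for a baseline
#'   grid, all > 0 for an enrichment grid).
#' @param h Numeric vector of approximate-heritability values in `[0, 1)`.
#' @return A `data.frame` of class `hyper_grid` with columns `theta0`,
#'   `theta`, `h` and uniform `weight` summing to 1.
#' @export
make_grid <- function(theta0, theta, h) {
  stopifnot(length(theta0) >= 1, length(theta) >= 1, length(h) >= 1,
            all(is.finite(theta0)), all(theta >= 0), all(h >= 0), all(h < 1))
  g <- expand.grid(theta0 = theta0, theta = theta, h = h,
                   KEEP.OUT.ATTRS = FALSE)
  if (any(g$theta > 0) && any(g$theta == 0))
    stop("a grid must be all-baseline (theta = 0) or all-enrichment (theta > 0)")
  g$weight <- 1 / nrow(g)
  class(g) <- c("hyper_grid", "data.frame")
  g
}

#' Default hyperparameter grids
#'
#' Defaults: `theta0` from -6 to -2 in steps of 0.25 (17 points), `theta`
#' from 0.5 to 3 in steps of 0.5 (6 points, enrichment mode only), and `h`
#' from 0.1 to 0.7 in steps of 0.1 (7 points).  The baseline grid is the
#' same `(theta0, h)` grid with `theta` fixed at 0, so the Bayes factor
#' contrasts only the enrichment parameter.
#'
#' @param mode `"baseline"` for the M0 grid (theta = 0) or `"enrichment"`
#'   for the M1 grid (theta > 0).
#' @return A `hyper_grid` (see [make_grid()]).
#' @export
default_grids <- function(mode = c("baseline", "enrichment")) {
  mode <- match.arg(mode)
  theta0 <- seq(-6, -2, by = 0.25)
  h <- seq(0.1, 0.7, by = 0.1)
  if (mode == "baseline") make_grid(theta0, 0, h)
  else make_grid(theta0, seq(0.5, 3, by = 0.5), h)
}

#' Read hyperparameter grids from a YAML configuration
#'
#' The file may specify each of `theta0`, `theta`, `h` either as an explicit
#' list of values or as a mapping with `min`, `max`, `step`.  Omitted
#' entries fall back to the package defaults.
#'
#' @param path Path to the YAML file.
#' @return List with elements `grid0` (baseline) and `grid1` (enrichment).
#' @export
read_grid_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading grid configurations requires the yaml package")
  cfg <- yaml::yaml.load_file(path)
  expand <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.list(x) && all(c("min", "max", "step") %in% names(x)))
      return(seq(x$min, x$max, by = x$step))
    as.numeric(unlist(x))
  }
  theta0 <- expand(cfg$theta0, seq(-6, -2, by = 0.25))
  theta <- expand(cfg$theta, seq(0.5, 3, by = 0.5))
  h <- expand(cfg$h, seq(0.1, 0.7, by = 0.1))
  list(grid0 = make_grid(theta0, 0, h), grid1 = make_grid(theta0, theta, h))
}
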