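#' Estimate pairwise sharing of pathway enrichments between two traits
#'
#' Each pathway j carries latent enrichment indicators `(z_1j, z_2j)` for
#' the two traits, with joint probabilities
#' `pi_ab = Pr(z_1j = a, z_2j = b)`.  Given the per-trait enrichment Bayes
#' factors, the marginal likelihood of the two BF vectors is
#' \deqn{\prod_j (\pi_{00} + \pi_{01}\mathrm{BF}_{2j} + \pi_{10}\mathrm{BF}_{1j}
#'   + \pi_{11}\mathrm{BF}_{1j}\mathrm{BF}_{2j}),}
#' maximized over the simplex by expectation-maximization: E-step
#' responsibilities proportional to the component terms, M-step the mean
#' responsibilities.  All arithmetic is in log space, so astronomically
#' large BFs are handled exactly.  With a constant likelihood (all BFs 1)
#' every point is stationary and the uniform initialization is returned
#' unchanged.
#'
#' @param bf1,bf2 Positive Bayes-factor vectors of equal length (one entry
#'   per pathway), or log10 Bayes factors with `log10 = TRUE`.
#' @param init Initial simplex point (default uniform).
#' @param tol Convergence tolerance on `max |change in pi|` (default 1e-8).
#' @param max_iter Maximum EM iterations (default 10000).
#' @param log10 Interpret `bf1`/`bf2` as log10 BFs (default `FALSE`).
#' @return Object of class `sharing_estimate`: `pi` (named `pi00`, `pi01`,
#'   `pi10`, `pi11`), `loglik` (natural log), `n_pathways`, `n_iter`,
#'   `converged`.
#' @export
sharing_em <- function(bf1, bf2, init = rep(0.25, 4), tol = 1e-8,
                       max_iter = 10000, log10 = FALSE) {
  stopifnot(length(bf1) == length(bf2), length(bf1) >= 1,
            length(init) == 4, all(init >= 0), abs(sum(init) - 1) < 1e-8)
  if (log10) {
    lb1 <- bf1 * log(10); lb2 <- bf2 * log(10)
  } else {
    if (any(bf1 <= 0) || any(bf2 <= 0)) stop("Bayes factors must be positive")
    lb1 <- log(bf1); lb2 <- log(bf2)
  }
  # log component likelihoods per pathway: (1, BF2, BF1, BF1*BF2)
  L <- cbind(0, lb2, lb1, lb1 + lb2)
  pi <- init
  loglik <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lw <- sweep(L, 2L, log(pmax(pi, 1e-300)), `+`)
    mx <- apply(lw, 1L, max)
    resp <- exp(lw - mx)
    rs <- rowSums(resp)
    loglik <- sum(mx + log(rs))
    pi_new <- colMeans(resp / rs)
    if (max(abs(pi_new - pi)) < tol) {
      pi <- pi_new
      converged <- TRUE
      break
    }
    pi <- pi_new
  }
  lw <- sweep(L, 2L, log(pmax(pi, 1e-300)), `+`)
  loglik <- sum(apply(lw, 1L, logsumexp))
  structure(list(pi = setNames(pi, c("pi00", "pi01", "pi10", "pi11")),
                 loglik = loglik, n_pathways = length(bf1), n_iter = it,
                 converged = converged),
            class = "sharing_estimate")
}

#' Conditional sharing statistic
#'
#' The probability that a pathway is enriched in both traits given it is
#' enriched in at least one: \eqn{\hat\pi_{11} / (1 - \hat\pi_{00})}.
#'
#' @param est A `sharing_estimate` from [sharing_em()].
#' @return Scalar in `[0, 1]`; error when `pi00 = 1` (no pathway enriched
#'   in either trait, so the statistic is undefined).
#' @export
conditional_sharing <- function(est) {
  stopifnot(inherits(est, "sharing_estimate"))
  if (est$pi[["pi00"]] >= 1 - 1e-12)
    stop("conditional sharing undefined: pi00 = 1")
  est$pi[["pi11"]] / (1 - est$pi[["pi00"]])
}

#' Pairwise conditional-sharing matrix across traits
#'
#' Applies [sharing_em()] to every pair of traits in a log10 Bayes-factor
#' matrix (rows = traits, columns = pathways) and returns the symmetric
#' matrix of conditional sharing statistics, with 1 on the diagonal by
#' convention.
#'
#' @param log10_bf_table Numeric matrix of log10 BFs with rownames naming
#'   the traits.
#' @param ... Passed to [sharing_em()].
#' @return List with `matrix` (traits x traits) and `pairs` (long-format
#'   data.frame of the upper triangle).
#' @export
pairwise_sharing_matrix <- function(log10_bf_table, ...) {
  stopifnot(is.matrix(log10_bf_table), nrow(log10_bf_table) >= 1)
  traits <- rownames(log10_bf_table) %||% paste0("trait", seq_len(nrow(log10_bf_table)))
  nt <- nrow(log10_bf_table)
  M <- diag(1, nt)
  dimnames(M) <- list(traits, traits)
  pairs <- list()
  if (nt >= 2) for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    est <- sharing_em(log10_bf_table[i, ], log10_bf_table[j, ],
                      log10 = TRUE, ...)
    cs <- conditional_sharing(est)
    M[i, j] <- M[j, i] <- cs
    pairs[[length(pairs) + 1L]] <-
      data.frame(trait1 = traits[i], trait2 = traits[j], sharing = cs,
                 pi00 = est$pi[[1]], pi01 = est$pi[[2]],
                 pi10 = est$pi[[3]], pi11 = est$pi[[4]],
                 stringsAsFactors = FALSE)
  }
  list(matrix = M,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(trait1 = character(0), trait2 = character(0),
                    sharing = numeric(0)))
}

#' @export
print.sharing_estimate <- function(x, ...) {
  cat("Sharing estimate over", x$n_pathways, "pathways:\n")
  print(round(x$pi, 4))
  cat("conditional sharing pi11/(1-pi00) =",
      format(tryCatch(conditional_sharing(x), error = function(e) NA),
             digits = 4), "\n")
  invisible(x)
}
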