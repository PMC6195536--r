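# Banded symmetric storage convention (shared with the C++ kernels):
# a (bw+1) x m matrix `band` with band[k+1, j] = A[j+k, j], k = 0..bw.

band_to_dense <- function(band) {
  m <- ncol(band); bw <- nrow(band) - 1L
  A <- matrix(0, m, m)
  for (k in 0:bw) {
    if (m - k < 1L) break
    idx <- seq_len(m - k)
    A[cbind(idx + k, idx)] <- band[k + 1L, idx]
    A[cbind(idx, idx + k)] <- band[k + 1L, idx]
  }
  A
}

dense_to_band <- function(A, bw) {
  m <- ncol(A)
  band <- matrix(0, bw + 1L, m)
  for (k in 0:min(bw, m - 1L)) {
    idx <- seq_len(m - k)
    band[k + 1L, idx] <- A[cbind(idx + k, idx)]
  }
  band
}

# Gershgorin-bracketed bisection on the banded Cholesky; used when a block is
# too large to expand densely.
band_min_eig <- function(band, tol = 1e-10) {
  m <- ncol(band); bw <- nrow(band) - 1L
  if (m <= 1500L) return(min(eigen(band_to_dense(band), symmetric = TRUE,
                                   only.values = TRUE)$values))
  absrow <- numeric(m)
  for (k in seq_len(bw)) {
    idx <- seq_len(m - k)
    a <- abs(band[k + 1L, idx])
    absrow[idx] <- absrow[idx] + a
    absrow[idx + k] <- absrow[idx + k] + a
  }
  lo <- min(band[1L, ] - absrow)
  hi <- max(band[1L, ] + absrow)
  shift_pd <- function(s) {
    b <- band; b[1L, ] <- b[1L, ] - s
    isTRUE(.band_chol(b)$ok)
  }
  if (!shift_pd(lo)) return(lo)
  while (hi - lo > tol * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (shift_pd(mid)) lo <- mid else hi <- mid
  }
  lo
}

map_cm_positions <- function(positions, chrom, map = NULL) {
  if (is.null(map)) return(positions * 1e-6)   # 1 cM/Mb fallback
  stopifnot(all(c("pos", "cm") %in% names(map)))
  cm <- numeric(length(positions))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    mp <- if ("chrom" %in% names(map)) map[map$chrom == ch, ] else map
    if (nrow(mp) < 2L) { cm[sel] <- positions[sel] * 1e-6; next }
    mp <- mp[order(mp$pos), ]
    if (is.unsorted(mp$cm)) stop("genetic map is not monotone in cM for chromosome ", ch)
    cm[sel] <- approx(mp$pos, mp$cm, xout = positions[sel], rule = 2)$y
  }
  cm
}

#' Per-SNP band extents and independent-block boundaries
#'
#' For each SNP, finds the furthest downstream SNP within `bandwidth_cm`
#' centimorgans (interpolated from `map`; without a map a 1 cM/Mb constant
#' rate is assumed, so the default bandwidth is a 1 Mb physical window).
#' Block boundaries are placed wherever consecutive band extents are
#' disjoint, which renders the banded LD matrix block-diagonal and lets each
#' block be fitted independently.
#'
#' @param positions Base-pair positions, sorted within chromosome.
#' @param chrom Chromosome label per SNP.
#' @param map Optional genetic map, a data.frame with columns `pos` (bp) and
#'   `cm` (and optionally `chrom`), monotone in `cm`.
#' @param bandwidth_cm Band half-width in centimorgans (default 1).
#' @return List with `ext` (integer vector; number of downstream SNPs within
#'   the bandwidth), `cm` (interpolated map positions) and `blocks` (a
#'   data.frame of `start`/`end` SNP indices).
#' @export
bandwidth_from_map <- function(positions, chrom, map = NULL, bandwidth_cm = 1) {
  p <- length(positions)
  stopifnot(p >= 1L, length(chrom) == p, bandwidth_cm > 0)
  cm <- map_cm_positions(positions, chrom, map)
  ext <- integer(p)
  starts <- integer(0)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    if (is.unsorted(positions[sel])) stop("positions not sorted within chromosome ", ch)
    cms <- cm[sel]
    # furthest j+k with cm[j+k] - cm[j] <= bandwidth
    ub <- findInterval(cms + bandwidth_cm, cms)
    ext[sel] <- ub - seq_along(sel)
    reach <- cummax(seq_along(sel) + ext[sel])
    brk <- which(reach[-length(sel)] <= seq_len(length(sel) - 1L))
    starts <- c(starts, sel[1L], sel[brk + 1L])
  }
  starts <- sort(unique(starts))
  ends <- c(starts[-1L] - 1L, p)
  list(ext = ext, cm = cm,
       blocks = data.frame(start = starts, end = ends))
}

banded_sample_cov <- function(X, ext) {
  band <- .band_sample_cov(X, as.integer(pmax(ext, 0L)))
  if (any(band[1L, ] <= 0))
    stop("monomorphic SNP(s) in reference panel block; filter by MAF first")
  band
}

#' Estimate a banded, positive-definite LD matrix from a reference panel
#'
#' Sample covariances are shrunk toward zero with the map-distance decay
#' \eqn{\exp(-\rho_{ij} / (2m))}, where \eqn{\rho_{ij} = 4 N_e d_{ij} / 100}
#' for genetic distance \eqn{d_{ij}} in cM, effective population size
#' \eqn{N_e} and panel haplotype count \eqn{m}; a small mutation-driven
#' diagonal adjustment is applied; entries beyond the bandwidth are set to
#' exactly zero; and each independent block is diagonally regularized to
#' positive definiteness and rescaled to unit diagonal.  Zero map distance
#' gives shrinkage factor 1 and the factor decays monotonically to 0.
#'
#' @param panel A reference panel from [load_reference_panel()] (or any list
#'   with a numeric `geno` matrix, a `snp` table with `chrom`/`pos`, and a
#'   `type` of `"haplotype"` or `"genotype"`).
#' @param map Optional genetic map (see [bandwidth_from_map()]).
#' @param bandwidth_cm Band half-width in cM (default 1; 1 Mb without a map).
#' @param ne Effective population size used in the shrinkage rate
#'   (default 11418, the conventional European-ancestry value); `ne = 0`
#'   disables distance shrinkage.
#' @param mutation_adjust Apply the mutation-rate diagonal adjustment
#'   (default `TRUE`); disable together with `ne = 0` to recover the plain
#'   sample correlation.
#' @param pd_tol Minimum eigenvalue enforced per block (default 1e-8).
#' @return An object of class `banded_ld`: a list of blocks (each with the
#'   banded correlation storage, its bandwidth and global SNP indices), the
#'   SNP table, and per-SNP band extents.
#' @export
estimate_shrunk_ld <- function(panel, map = NULL, bandwidth_cm = 1,
                               ne = 11418, mutation_adjust = TRUE,
                               pd_tol = 1e-8) {
  X <- panel$geno
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  snp <- panel$snp
  m_hap <- if (identical(panel$type, "genotype")) 2L * nrow(X) else nrow(X)
  bwi <- bandwidth_from_map(snp$pos, snp$chrom, map, bandwidth_cm)
  blocks <- vector("list", nrow(bwi$blocks))
  for (b in seq_len(nrow(bwi$blocks))) {
    i0 <- bwi$blocks$start[b]; i1 <- bwi$blocks$end[b]
    idx <- i0:i1
    ext <- pmin(bwi$ext[idx], i1 - idx)   # extents clipped to the block
    band <- banded_sample_cov(X[, idx, drop = FALSE], ext)
    bw <- nrow(band) - 1L
    m <- length(idx)
    # distance shrinkage of off-diagonal covariances
    if (ne > 0 && bw > 0L) {
      cms <- bwi$cm[idx]
      for (k in seq_len(bw)) {
        j <- seq_len(m - k)
        d <- cms[j + k] - cms[j]
        band[k + 1L, j] <- band[k + 1L, j] * exp(-(4 * ne * d / 100) / (2 * m_hap))
      }
    }
    if (mutation_adjust) {
      nmsum <- sum(1 / seq_len(max(m_hap - 1L, 1L)))
      theta_m <- (1 / nmsum) / (m_hap + 1 / nmsum)
      band <- (1 - theta_m)^2 * band
      band[1L, ] <- band[1L, ] + (theta_m / 2) * (1 - theta_m / 2)
    }
    # covariance -> correlation
    sdv <- sqrt(band[1L, ])
    for (k in seq_len(bw)) {
      j <- seq_len(m - k)
      band[k + 1L, j] <- band[k + 1L, j] / (sdv[j] * sdv[j + k])
    }
    band[1L, ] <- 1
    # enforce exact banding at the per-SNP extent
    for (k in seq_len(bw)) {
      j <- seq_len(m - k)
      band[k + 1L, j][ext[j] < k] <- 0
    }
    shifted <- band
    shifted[1L, ] <- shifted[1L, ] - pd_tol
    lambda <- if (isTRUE(.band_chol(shifted)$ok)) 0 else
      max(0, pd_tol - band_min_eig(band))
    if (lambda > 0) {
      band[1L, ] <- band[1L, ] + lambda
      band <- band / (1 + lambda)         # back to unit diagonal, still PD
    }
    if (!isTRUE(.band_chol(band)$ok))
      stop("LD block ", b, " is not positive-definite after regularization")
    blocks[[b]] <- list(chrom = snp$chrom[i0], idx = idx, band = band,
                        bw = bw, lambda = lambda)
  }
  structure(list(blocks = blocks, p = ncol(X), snp = snp, ext = bwi$ext,
                 bandwidth_cm = bandwidth_cm),
            class = "banded_ld")
}

#' Positive-definiteness report for a banded LD matrix
#'
#' @param ld A `banded_ld` object.
#' @return data.frame with one row per block: size, bandwidth, minimum
#'   eigenvalue and a PD flag.
#' @export
validate_psd <- function(ld) {
  stopifnot(inherits(ld, "banded_ld"))
  out <- lapply(seq_along(ld$blocks), function(b) {
    blk <- ld$blocks[[b]]
    me <- band_min_eig(blk$band)
    data.frame(block = b, chrom = blk$chrom, size = length(blk$idx),
               bandwidth = blk$bw, min_eig = me, pd = me > 0)
  })
  do.call(rbind, out)
}

#' @export
print.banded_ld <- function(x, ...) {
  cat("Banded LD matrix:", x$p, "SNPs,", length(x$blocks), "block(s),",
      "max bandwidth", max(vapply(x$blocks, `[[`, 0L, "bw")), "SNPs\n")
  invisible(x)
}

#' Read a tab-delimited genetic map
#'
#' Expects columns `pos` (bp) and `cm`, optionally `chrom`.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return data.frame usable as the `map` argument of
#'   [estimate_shrunk_ld()].
#' @export
read_genetic_map <- function(path) {
  mp <- as.data.frame(data.table::fread(path))
  if (!all(c("pos", "cm") %in% names(mp)))
    stop("genetic map must have columns `pos` and `cm`")
  mp
}
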