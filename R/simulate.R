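# latent-Gaussian AR(1) haplotypes: correlation decays by `rho` per adjacent
# SNP; allele frequency of SNP j is maf[j]
ar_haplotypes <- function(n_hap, p, rho, maf) {
  Z <- matrix(0, n_hap, p)
  Z[, 1L] <- rnorm(n_hap)
  if (p > 1L) {
    sd_innov <- sqrt(1 - rho^2)
    for (j in 2:p) Z[, j] <- rho * Z[, j - 1L] + sd_innov * rnorm(n_hap)
  }
  thr <- qnorm(maf)
  storage.mode(Z) <- "double"
  H <- sweep(Z, 2L, thr, `<`) * 1L
  H
}

#' Simulate genotypes with autoregressive LD
#'
#' Haplotypes follow a latent-Gaussian first-order autoregressive model:
#' adjacent SNPs have latent correlation `ld_decay`, so LD decays
#' geometrically with SNP distance.  Allele frequencies are uniform in
#' `maf_range` and positions are equally spaced (`spacing_bp`, default
#' 10 kb) on a single synthetic chromosome with a constant 1 cM/Mb map.
#'
#' @param n Number of diploid individuals.
#' @param p Number of SNPs.
#' @param ld_decay Latent adjacent-SNP correlation in `[0, 1)`
#'   (default 0.9); 0 gives independent SNPs.
#' @param maf_range Range of allele frequencies (default 0.05-0.5).
#' @param seed Integer seed.
#' @param spacing_bp Inter-SNP spacing in bp (default 10,000).
#' @param chrom Chromosome label (default "1").
#' @return List with `geno` (n x p dosage matrix), `maf`, `positions`,
#'   `chrom` (vector), `map` (data.frame `pos`, `cm`), and `snp` (id table).
#' @export
simulate_genotypes <- function(n, p, ld_decay = 0.9, maf_range = c(0.05, 0.5),
                               seed = 1, spacing_bp = 10000, chrom = "1") {
  stopifnot(n >= 2, p >= 1, ld_decay >= 0, ld_decay < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(seed)
  maf <- runif(p, maf_range[1], maf_range[2])
  H <- ar_haplotypes(2L * n, p, ld_decay, maf)
  geno <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  positions <- seq_len(p) * spacing_bp
  list(geno = geno, maf = maf, positions = positions,
       chrom = rep(chrom, p),
       map = data.frame(pos = positions, cm = positions * 1e-6),
       snp = data.frame(snp_id = sprintf("rs%06d", seq_len(p)),
                        chrom = rep(chrom, p), pos = positions,
                        ref = "A", alt = "C", stringsAsFactors = FALSE))
}

#' Simulate an external reference panel matching a genotype simulation
#'
#' Draws haplotypes independently from the same autoregressive population
#' model, mimicking an external LD reference panel of matched ancestry.
#'
#' @param geno_sim Output of [simulate_genotypes()].
#' @param n_hap Number of panel haplotypes (default 400).
#' @param seed Integer seed.
#' @param ld_decay Latent adjacent-SNP correlation (same default as the
#'   study genotypes).
#' @return A `ref_panel` (type `"haplotype"`).
#' @export
simulate_panel <- function(geno_sim, n_hap = 400, seed = 2, ld_decay = 0.9) {
  set.seed(seed)
  H <- ar_haplotypes(n_hap, length(geno_sim$maf), ld_decay, geno_sim$maf)
  structure(list(geno = H, snp = geno_sim$snp, type = "haplotype",
                 ancestry = "synthetic"),
            class = "ref_panel")
}

#' Define a simulation scenario
#'
#' Bundles the generating conditions for one benchmark design: the genetic
#' architecture (`sparse`: 50 expected causal SNPs; `polygenic`: 1% of
#' SNPs), the baseline/enrichment pattern, and the enrichment strength.
#' Patterns: `"a"` — baseline data follow the no-enrichment model and
#' enrichment data the enrichment model for the target set; `"b"` —
#' baseline data are themselves enriched in a random near-gene SNP set;
#' `"c"` — baseline data are enriched in a random set of coding-labeled
#' SNPs (a random 1.5% of SNPs stand in for a coding annotation); `"d"` —
#' enrichment data have causal SNPs that are both more frequent and have
#' `effect_multiplier`-fold larger effect standard deviation inside the
#' target set.
#'
#' @param architecture `"sparse"` or `"polygenic"`.
#' @param pattern `"a"`, `"b"`, `"c"` or `"d"`.
#' @param n,p Individuals and SNPs (defaults 5000 and 5000).
#' @param theta Enrichment parameter of the generating model (default 2).
#' @param h Proportion of phenotypic variance explained by genotype
#'   (default 0.3).
#' @param n_genes Number of genes laid out along the chromosome (default
#'   `p / 25`).
#' @param set_fraction Fraction of genes in the target set (default 0.1).
#' @param effect_multiplier Inside-set effect-size multiplier for pattern
#'   `"d"` (default 1.5; 1 reduces `"d"` to `"a"`).
#' @param ld_decay,maf_range,spacing_bp See [simulate_genotypes()].
#' @param coding_fraction Fraction of SNPs given the synthetic coding label
#'   in pattern `"c"` (default 0.015).
#' @param window Annotation window in bp (default 100,000).
#' @param n_panel_hap Reference-panel haplotypes (default 400).
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(architecture = c("sparse", "polygenic"),
                         pattern = c("a", "b", "c", "d"),
                         n = 5000, p = 5000, theta = 2, h = 0.3,
                         n_genes = max(2L, round(p / 25)),
                         set_fraction = 0.1, effect_multiplier = 1.5,
                         ld_decay = 0.9, maf_range = c(0.05, 0.5),
                         spacing_bp = 10000, coding_fraction = 0.015,
                         window = 100000, n_panel_hap = 400) {
  architecture <- match.arg(architecture)
  pattern <- match.arg(pattern)
  stopifnot(n > 0, p > 0, theta >= 0, h > 0, h < 1, effect_multiplier > 0)
  if (pattern == "d" && effect_multiplier < 1)
    stop("pattern d requires an inside-set effect multiplier >= 1")
  structure(list(architecture = architecture, pattern = pattern, n = n,
                 p = p, theta = theta, h = h, n_genes = n_genes,
                 set_fraction = set_fraction,
                 effect_multiplier = effect_multiplier, ld_decay = ld_decay,
                 maf_range = maf_range, spacing_bp = spacing_bp,
                 coding_fraction = coding_fraction, window = window,
                 n_panel_hap = n_panel_hap),
            class = "sim_scenario")
}

expected_causal <- function(scenario) {
  if (scenario$architecture == "sparse") 50 else 0.01 * scenario$p
}

# theta0 such that the expected number of causal SNPs matches the target
solve_theta0 <- function(target, theta, a) {
  f <- function(t0) sum(prior_inclusion_probs(t0, theta, a)) - target
  uniroot(f, c(-14, 8), tol = 1e-10)$root
}

#' Draw true SNP effects for a simulation scenario
#'
#' Causal indicators are Bernoulli with the enrichment-prior probabilities
#' (background log10-odds solved so that the expected causal count matches
#' the architecture: 50 for sparse, 1% of SNPs for polygenic); causal
#' effects are normal with variance set from `h` through the slab-variance
#' relation, using panel genotype variances in place of the yet-unobserved
#' standard errors.  For pattern `"d"` enrichment draws, causal effects of
#' inside-set SNPs get `effect_multiplier`-fold larger standard deviation.
#'
#' @param scenario A `sim_scenario`.
#' @param annotation `snp_annotation` (or binary vector) receiving the
#'   enrichment, or `NULL` for a no-enrichment draw.
#' @param geno Genotype matrix (used for per-SNP variances).
#' @param multiplier Inside-set effect-sd multiplier (default 1).
#' @return List with `beta`, `causal` (indices), `theta0`, `pi`,
#'   `sigma_beta2`.
#' @export
draw_effects <- function(scenario, annotation = NULL, geno, multiplier = 1) {
  p <- scenario$p
  a <- if (is.null(annotation)) rep(0, p) else annotation_vector(annotation)
  theta <- if (is.null(annotation)) 0 else scenario$theta
  theta0 <- solve_theta0(expected_causal(scenario), theta, a)
  pi <- prior_inclusion_probs(theta0, theta, a)
  vg <- apply(geno, 2L, var)
  sigma_beta2 <- scenario$h / sum(pi * vg)
  causal <- which(runif(p) < pi)
  beta <- numeric(p)
  sd_j <- sqrt(sigma_beta2) * ifelse(a[causal] == 1, multiplier, 1)
  beta[causal] <- rnorm(length(causal), 0, sd_j)
  list(beta = beta, causal = causal, theta0 = theta0, pi = pi,
       sigma_beta2 = sigma_beta2)
}

#' Single-SNP summary statistics from individual-level data
#'
#' Per-SNP simple linear regression of the centered phenotype on the
#' centered genotype: \eqn{\hat\beta_j = x_j'y / x_j'x_j} and
#' \eqn{\hat s_j^2 = \mathrm{residual\ variance} / x_j'x_j}.  A perfect fit
#' (zero residual) gets its standard error floored at `se_floor` and is
#' flagged in the `se_floored` attribute.
#'
#' @param genotypes n x p dosage matrix.
#' @param phenotype Length-n numeric vector.
#' @param snp_info Optional data.frame with `snp_id`, `chrom`, `pos` (and
#'   optionally `ref`/`alt`, used as the allele columns).
#' @param se_floor Lower bound for standard errors (default 1e-12).
#' @return A summary-statistic data.frame in the standard layout.
#' @export
single_snp_summary_stats <- function(genotypes, phenotype, snp_info = NULL,
                                     se_floor = 1e-12) {
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  stopifnot(length(phenotype) == n, n > 2)
  xc <- sweep(genotypes, 2L, colMeans(genotypes))
  yc <- phenotype - mean(phenotype)
  ssx <- colSums(xc^2)
  if (any(ssx == 0)) stop("monomorphic genotype column(s): cannot regress")
  ssy <- sum(yc^2)
  betahat <- colSums(xc * yc) / ssx
  rss <- pmax(ssy - betahat^2 * ssx, 0)
  se <- sqrt(rss / (n - 2) / ssx)
  floored <- se < se_floor
  se[floored] <- se_floor
  if (is.null(snp_info))
    snp_info <- data.frame(snp_id = sprintf("rs%06d", seq_len(p)),
                           chrom = "1", pos = seq_len(p) * 10000L,
                           stringsAsFactors = FALSE)
  out <- data.frame(snp_id = snp_info$snp_id, chrom = snp_info$chrom,
                    pos = snp_info$pos,
                    allele_effect = snp_info$alt %||% rep("C", p),
                    allele_other = snp_info$ref %||% rep("A", p),
                    betahat = betahat, se = se, n = n,
                    stringsAsFactors = FALSE)
  attr(out, "se_floored") <- sum(floored)
  out
}

simulate_gene_layout <- function(positions, chrom, n_genes,
                                 span_range = c(5000, 50000)) {
  lo <- min(positions); hi <- max(positions)
  span <- runif(n_genes, span_range[1], span_range[2])
  start <- round(runif(n_genes, lo, pmax(lo + 1, hi - span)))
  g <- data.frame(gene = sprintf("G%04d", seq_len(n_genes)),
                  chrom = chrom[1], start = start,
                  end = round(start + span), strand = "+",
                  stringsAsFactors = FALSE)
  g[order(g$start), ]
}

#' Simulate a complete study under a benchmark scenario
#'
#' Generates genotypes, a matched external reference panel, a gene layout
#' with a target gene set, true effects according to the scenario pattern
#' and arm, a phenotype with the scenario's heritability, and the derived
#' single-SNP summary statistics.  Truth labels record the causal SNPs and
#' the trait-associated genes (a gene is associated iff at least one causal
#' SNP lies within the window of its transcribed region).
#'
#' @param scenario A `sim_scenario`.
#' @param arm `"enrichment"` (the target set is enriched) or `"baseline"`
#'   (no target-set enrichment; patterns `"b"`/`"c"` enrich a decoy set).
#' @param seed Integer seed controlling all draws.
#' @return Object of class `sim_study` with elements `stats`, `panel`,
#'   `genes`, `gene_set` (member symbols of the target set), `annotation`,
#'   `map`, `geno`, `phenotype`, `beta`, `truth`
#'   (list: `causal_snps`, `associated_genes`, `theta0`, `sigma_beta2`),
#'   `scenario`, `arm`.
#' @export
simulate_study <- function(scenario, arm = c("enrichment", "baseline"),
                           seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  arm <- match.arg(arm)
  gs <- simulate_genotypes(scenario$n, scenario$p, scenario$ld_decay,
                           scenario$maf_range, seed = seed,
                           spacing_bp = scenario$spacing_bp)
  panel <- simulate_panel(gs, n_hap = scenario$n_panel_hap,
                          seed = seed + 1000003L, ld_decay = scenario$ld_decay)
  set.seed(seed + 2000003L)
  genes <- simulate_gene_layout(gs$positions, gs$chrom, scenario$n_genes)
  n_set <- max(2L, round(scenario$set_fraction * nrow(genes)))
  gene_set <- sort(sample(genes$gene, n_set))
  pos_df <- data.frame(snp_id = gs$snp$snp_id, chrom = gs$chrom,
                       pos = gs$positions, stringsAsFactors = FALSE)
  target_ann <- suppressMessages(
    build_snp_annotation(gene_set, genes, pos_df, window = scenario$window,
                         set_name = "target_set"))
  set.seed(seed + 3000017L)
  eff_ann <- NULL
  multiplier <- 1
  if (arm == "enrichment") {
    eff_ann <- target_ann
    if (scenario$pattern == "d") multiplier <- scenario$effect_multiplier
  } else if (scenario$pattern == "b") {
    universe <- all_genes_annotation(genes, pos_df, scenario$window)
    eff_ann <- random_matched_null_set(universe, target_ann$n_inside,
                                       seed = seed + 4000037L)
  } else if (scenario$pattern == "c") {
    a <- integer(scenario$p)
    a[sample(scenario$p, max(1L, round(scenario$coding_fraction * scenario$p)))] <- 1L
    eff_ann <- a
  }
  eff <- draw_effects(scenario, eff_ann, gs$geno, multiplier = multiplier)
  g_comp <- drop(gs$geno %*% eff$beta)
  if (var(g_comp) > 0) {
    sigma_e <- sqrt(var(g_comp) * (1 - scenario$h) / scenario$h)
    y <- g_comp + rnorm(scenario$n, 0, sigma_e)
  } else y <- rnorm(scenario$n)
  stats <- single_snp_summary_stats(gs$geno, y, snp_info = gs$snp)
  causal <- eff$causal
  assoc <- genes$gene[vapply(seq_len(nrow(genes)), function(i) {
    any(gs$positions[causal] >= genes$start[i] - scenario$window &
        gs$positions[causal] <= genes$end[i] + scenario$window)
  }, TRUE)]
  structure(list(stats = stats, panel = panel, genes = genes,
                 gene_set = gene_set, annotation = target_ann, map = gs$map,
                 geno = gs$geno, phenotype = y, beta = eff$beta,
                 truth = list(causal_snps = causal, associated_genes = assoc,
                              theta0 = eff$theta0,
                              sigma_beta2 = eff$sigma_beta2),
                 scenario = scenario, arm = arm, seed = seed),
            class = "sim_study")
}

#' Rank-based AUC separating two score sets
#'
#' The probability that a randomly chosen enrichment-dataset score exceeds
#' a randomly chosen baseline-dataset score, ties counting one half —
#' i.e. the area under the ROC curve of the scores as a classifier of
#' dataset arm.
#'
#' @param scores_baseline,scores_enrichment Numeric score vectors (e.g.
#'   log10 Bayes factors of baseline-arm and enrichment-arm datasets).
#' @return AUC in `[0, 1]`; 0.5 means no separation.
#' @export
evaluate_auc <- function(scores_baseline, scores_enrichment) {
  n0 <- length(scores_baseline); n1 <- length(scores_enrichment)
  stopifnot(n0 >= 1, n1 >= 1)
  r <- rank(c(scores_enrichment, scores_baseline))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Write a simulated study to disk as a self-contained fixture
#'
#' Emits the summary statistics (TSV), reference panel (VCF), gene spans
#' (BED), the target gene set (GMT), the genetic map (TSV) and the truth
#' labels (JSON) into a directory, in the exact formats the readers of this
#' package consume.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_study_fixture <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stats = file.path(dir, "sumstats.tsv"),
             panel = file.path(dir, "panel.vcf"),
             genes = file.path(dir, "genes.bed"),
             sets = file.path(dir, "gene_sets.gmt"),
             map = file.path(dir, "genetic_map.tsv"),
             truth = file.path(dir, "truth.json"))
  st <- study$stats
  data.table::fwrite(
    data.frame(snp = st$snp_id, chr = st$chrom, pos = st$pos,
               a1 = st$allele_effect, a2 = st$allele_other,
               betahat = st$betahat, se = st$se, n = st$n),
    paths["stats"], sep = "\t", quote = FALSE)
  write_panel_vcf(study$panel, paths["panel"])
  data.table::fwrite(
    data.frame(chrom = study$genes$chrom, start = study$genes$start - 1L,
               end = study$genes$end, name = study$genes$gene, score = 0,
               strand = study$genes$strand),
    paths["genes"], sep = "\t", col.names = FALSE, quote = FALSE)
  writeLines(paste(c("target_set", "simulated target gene set",
                     study$gene_set), collapse = "\t"), paths["sets"])
  data.table::fwrite(study$map, paths["map"], sep = "\t", quote = FALSE)
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write a reference panel as a phased VCF
#'
#' @param panel A `ref_panel` with haplotype data (type `"haplotype"`,
#'   even number of rows) or genotype data (written unphased).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  snp <- panel$snp
  p <- nrow(snp)
  if (identical(panel$type, "haplotype")) {
    nh <- nrow(panel$geno)
    stopifnot(nh %% 2 == 0)
    ni <- nh %/% 2
    gt <- sapply(seq_len(ni), function(i)
      paste0(panel$geno[2 * i - 1, ], "|", panel$geno[2 * i, ]))
  } else {
    ni <- nrow(panel$geno)
    gt <- sapply(seq_len(ni), function(i) {
      g <- panel$geno[i, ]
      c("0/0", "0/1", "1/1")[g + 1L]
    })
  }
  gt <- matrix(gt, nrow = p)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sprintf("S%04d", seq_len(ni))),
                    collapse = "\t"))
  body <- paste(snp$chrom, snp$pos, snp$snp_id, snp$ref, snp$alt, ".",
                "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
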