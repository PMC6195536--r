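---
title: "Model and methods behind gsenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind gsenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsenrich)
```

## The problem

Genome-wide association studies (GWAS) routinely release only summary
statistics: for each SNP $j$, a marginal effect estimate $\hat\beta_j$ and
its standard error $\hat s_j$ from a single-SNP regression on $n$
individuals.  Two questions this package answers from those summaries plus
an external linkage-disequilibrium (LD) reference panel:

1. **Enrichment** — are SNPs near the genes of a given set (a pathway, the
   genes expressed in a tissue, ...) more often associated with the trait
   than background SNPs?
2. **Prioritization** — given an inferred enrichment, which member genes
   drive it?

## The model

### Likelihood

The vector of single-SNP estimates is modeled jointly through the
multivariate normal likelihood

$$\hat{\boldsymbol\beta} \sim
N\!\left(\hat S \hat R \hat S^{-1} \boldsymbol\beta,\; \hat S \hat R \hat S\right),$$

where $\hat S = \mathrm{diag}(\hat s)$, $\hat R$ is the LD (correlation)
matrix estimated from a reference panel of matching ancestry, and
$\boldsymbol\beta$ are the true multi-SNP effects.  This is the standard
"regression with summary statistics" likelihood: it accounts for the fact
that SNPs in LD carry largely redundant marginal evidence, so a cluster of
correlated hits is treated as essentially one observation.
Algebraically it is an exponential family in $\boldsymbol\beta$ with natural
parameters $q = \hat S^{-2}\hat\beta$ and precision
$H = \hat S^{-1}\hat R\hat S^{-1}$ (`to_canonical()`); all fitting works in
that canonical form.

### Prior

Each SNP's effect follows a spike-and-slab mixture

$$\beta_j \sim \pi_j\, N(0, \sigma_\beta^2) + (1-\pi_j)\,\delta_0,
\qquad
\pi_j = \left(1 + 10^{-(\theta_0 + a_j \theta)}\right)^{-1},$$

with $a_j \in \{0,1\}$ indicating whether SNP $j$ lies within 100 kb of the
transcribed region of a gene in the set.  $\theta_0$ is the background
log10-odds of association; $\theta \ge 0$ is the enrichment parameter —
$\theta = 2$ means annotated SNPs have 100-fold higher prior odds of
association.  The slab variance is tied to an approximate-heritability
parameter $h$ by

$$\sigma_\beta^2 = h \cdot
\left(\sum_j \pi_j\, n_j^{-1} \hat s_j^{-2}\right)^{-1},$$

so that at fixed $h$ a more polygenic prior (larger $\sum\pi_j$) implies
smaller per-SNP effects.  The baseline model $M_0$ fixes $\theta = 0$; the
enrichment model $M_1$ has $\theta > 0$.  Evidence for enrichment is the
Bayes factor averaging each model's likelihood over an independent uniform
grid prior on $(\theta_0, \theta, h)$.

## Inference

### Variational approximation

For each grid point, the conditional posterior of $\boldsymbol\beta$ is
approximated by the fully factorized spike-and-slab family
$q_j = (\alpha_j, \mu_j, s_j^2)$ fitted by coordinate ascent on the evidence
lower bound.  The per-SNP updates are

$$s_j^2 = \frac{\sigma_\beta^2}{\sigma_\beta^2 H_{jj} + 1},\qquad
\mu_j = s_j^2\Big(q_j - \sum_{k \ne j} H_{jk}\,\alpha_k \mu_k\Big),\qquad
\mathrm{logit}\,\alpha_j = \mathrm{logit}\,\pi_j
 + \tfrac12\log\frac{s_j^2}{\sigma_\beta^2} + \frac{\mu_j^2}{2 s_j^2},$$

with the running residual $\sum_k H_{jk}\alpha_k\mu_k$ maintained
incrementally inside the LD band (the inner loop is compiled code).  The
lower bound is available in closed form and never exceeds the exact log
marginal likelihood; an enumeration oracle
(`exact_log_marginal_oracle()`) verifies this on every test run for
instances up to $p = 12$.

Numerical choices, each exposed as an argument:

* **Initialization.**  $\alpha_j \sim U(0,1)$,
  $\mu_j \sim N(0, \sigma_\beta)$ from a fixed seed (default 42); a single
  draw is shared by every grid point (with $\mu$ rescaled to each point's
  $\sigma_\beta$), so grid evidence differences reflect the prior, not the
  start.
* **Update order.**  Passes alternate forward/backward over the SNPs to
  reduce order bias.
* **Acceleration.**  Squared-extrapolation (SQUAREM-style) steps on
  $(\alpha, \mu)$ with a safeguard: any extrapolation that lowers the bound
  falls back to the plain coordinate update, so the bound remains monotone.
  The objective is non-convex; on rare instances the accelerated and plain
  paths settle in different local optima, which is inherent to coordinate
  ascent in spike-and-slab models.
* **Convergence.**  `max |change in alpha|` and `max |change in alpha*mu|`
  below `tol` (default 1e-4) — parameter-based, hence cheap and scale-free.
  Hitting `max_iter` (default 200 outer iterations) warns rather than fails.

### Grid posterior, Bayes factor, reuse

Per-point lower bounds stand in for log marginal likelihoods: normalized
with log-sum-exp they give a discrete posterior over $(\theta_0, \theta, h)$
(posterior means and 95% credible intervals by weighted grid quantiles), and

$$\log_{10}\mathrm{BF} =
\log_{10}\overline{e^{\mathrm{bound}}}\big|_{M_1} -
\log_{10}\overline{e^{\mathrm{bound}}}\big|_{M_0}.$$

Scanning thousands of gene sets re-uses the genome-wide baseline fits: the
enrichment fit at $(\theta_0, \theta, h)$ starts from the baseline fit at
$(\theta_0, h)$ and, by default, only updates SNPs inside the annotation
plus SNPs sharing an LD band with them.  This is accurate when the
annotation covers a small fraction of the genome (the operating regime —
a gene set typically annotates a few percent of SNPs); `reuse = FALSE`
refits everything for validation.  Default grids are $\theta_0 \in
\{-6, -5.75, \dots, -2\}$, $\theta \in \{0.5, 1, \dots, 3\}$, $h \in
\{0.1, \dots, 0.7\}$; any grid can be supplied.

### LD estimation

$\hat R$ comes from a shrinkage estimator on the panel's sample
correlations: off-diagonal entries are damped by
$\exp(-\rho_{ij}/(2m))$ with $\rho_{ij} = 4 N_e d_{ij}/100$ for genetic
distance $d_{ij}$ (cM), $N_e = 11418$ by default, and $m$ the panel
haplotype count, plus a small mutation-driven diagonal adjustment.  Entries
beyond a 1 cM bandwidth (1 Mb when no genetic map is given) are set to
exactly zero, which renders the matrix block diagonal: blocks are detected
where band extents become disjoint and are fitted independently.  Each
block is regularized by the smallest diagonal inflation
$\lambda = \max(0, 10^{-8} - \lambda_{\min})$ that restores positive
definiteness, then rescaled to unit diagonal.

### Locus statistics

For each gene, its locus is the set of analyzed SNPs within 100 kb of the
transcribed region (window boundaries inclusive; gene spans are unions over
transcripts; strand is ignored since the rule is symmetric; a SNP may
belong to several loci).  Two statistics summarize the posterior:

$$P_1 = 1 - \Pr(\beta_j = 0\ \forall j \in \mathrm{locus} \mid D), \qquad
\mathrm{ENS} = \sum_{j \in \mathrm{locus}} \Pr(\beta_j \ne 0 \mid D),$$

each averaged over the corresponding model's grid posterior ($M_0$ grid for
the baseline column, $M_1$ for the enrichment column).  Within a grid point
the variational posterior factorizes over SNPs, so the product form of
$P_1$ is exact under the approximation — a caveat documented rather than
corrected, since within-locus dependence is only captured through the
fitted means.  Genes with enrichment $P_1 > 0.9$ are flagged as signals.

### Cross-trait sharing

Given two traits' per-pathway enrichment Bayes factors, the latent
enrichment indicators' joint distribution
$\pi_{ab} = \Pr(z_{1j} = a, z_{2j} = b)$ is estimated by maximizing
$\prod_j(\pi_{00} + \pi_{01}\mathrm{BF}_{2j} + \pi_{10}\mathrm{BF}_{1j} +
\pi_{11}\mathrm{BF}_{1j}\mathrm{BF}_{2j})$ with a log-space EM
(responsibilities proportional to component terms; M-step means).  The
reported statistic is $\hat\pi_{11}/(1-\hat\pi_{00})$: the probability a
pathway is enriched in both traits given enrichment in at least one.  The
model assumes independence across pathways, which overlapping pathways
violate; estimates on strongly overlapping collections should be read as
descriptive.  With a constant likelihood the EM returns its uniform
initialization — the natural uninformative answer.

### Sanity checks

Large Bayes factors can reflect generic genic enrichment or model
misspecification rather than set-specific signal, so
`run_sanity_suite()` compares each set's BF against (i) the BF of the
all-genes annotation and (ii) the 95th percentile of BFs of 20 random
size-matched near-gene SNP sets, and attaches a likelihood-ratio contrast
of inside vs outside z-scores under the two-component scale mixture
$z \sim (1-\pi)N(0,1) + \pi N(0, 1+\sigma^2)$, fitted separately and with
shared parameters.  The LR ignores LD, so it is a cross-check, not a
substitute for the BF; no reference p-value is attached by default.

## The synthetic-data generator

`simulate_study()` emulates the benchmark designs used to validate the
method: haplotypes from a latent-Gaussian AR(1) model (adjacent-SNP
correlation 0.9 by default, geometric LD decay), allele frequencies uniform
on [0.05, 0.5], SNPs every 10 kb on a synthetic chromosome with a 1 cM/Mb
map, genes of 5–50 kb placed uniformly (one gene per 25 SNPs), a target set
of 10% of genes, and an independent reference panel of 400 haplotypes drawn
from the same population model.  Effects follow the enrichment prior
itself: the background log10-odds is solved so the expected causal count
matches the architecture — 50 causal SNPs ("sparse") or 1% of SNPs
("polygenic") — and the slab variance follows from the target heritability
(default $h = 0.3$, $n = 5000$, $p = 5000$, $\theta = 2$).  Pattern
variants: `b` and `c` enrich a decoy near-gene or synthetic-coding set in
the baseline arm (testing robustness to misspecified nulls); `d` both
enriches and inflates inside-set effect sizes 1.5-fold.  The "coding"
labels are a random 1.5% of SNPs — exercising the design needs no real
exome annotation.

What the generator does **not** emulate: realistic recombination hotspots
and LD block structure, allele-frequency-dependent effect sizes,
population stratification, imputation noise, overlapping gene sets, or
cross-chromosome layout.  Passing benchmarks therefore demonstrate
correctness of the inference machinery under the model and robustness to
the specific misspecifications of patterns b–d, not performance on any
particular real cohort.

## Problem sizes used in the checked examples

The test suite runs end-to-end benchmarks at sizes a single CPU handles
comfortably, chosen once as the package's validation conditions: parameter
recovery at $n = p = 5000$ over 5 seeds; discrimination benchmarks (30
baseline + 30 enrichment datasets per architecture) and null calibration
(40 matched null sets; 120 null datasets) at $n = p = 2000$ with a
$\theta_0 \in \{-3.5,\dots,-2\} \times \theta \in \{1,2,3\} \times h \in
\{0.2, 0.4\}$ grid; enumeration cross-checks at $p \le 12$.  The finer
default grids are used for single-dataset analyses; grid resolution mainly
affects the smoothness of the hyperparameter posterior, not the sign or
order of Bayes factors.

## Known limitations

* Summary statistics and LD panel must match in ancestry and variant
  orientation; `harmonize_alleles()` drops strand-ambiguous (A/T, C/G)
  SNPs rather than attempting frequency-based rescue.
* The MHC exclusion window is a fixed generous default
  (chr6:25–35 Mb, GRCh37) since the region's long-range LD violates the
  banded model; SNPs typed only on custom arrays cannot be detected without
  array metadata and are not handled.
* One annotation is modeled at a time; jointly modeling multiple
  overlapping annotations is out of scope.
* Per-locus posterior probabilities inherit the factorized variational
  approximation; for fine-mapping individual variants, use a dedicated
  fine-mapping method downstream.
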