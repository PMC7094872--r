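---
title: "Methods: from single-cell fluorescence to variability QTLs and causal screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell fluorescence to variability QTLs and causal screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vprotqtl)
```

# The problem

Two people with the same *average* expression of a surface protein on, say,
their CD4+ T cells can differ markedly in how *variable* that expression is
from cell to cell. `vprotqtl` implements a complete quantitative-genetic
analysis of this cell-to-cell variability as measured by flow cytometry:
it turns raw per-cell fluorescence events into a per-individual,
mean-adjusted variability statistic (η_res), asks how heritable that
statistic is in twin cohorts (ACE decomposition), maps genetic loci
associated with it (variability QTLs, via linear mixed models), and tests
whether *trans* variability signals are explained by *cis* effects on the
mean expression of nearby genes (two-sample Mendelian randomization).

Every stage is driven by a synthetic-data generator with known ground
truth, so the whole pipeline is testable on a laptop without any
access-restricted cohort data.

# Cytometry preprocessing

The fixed stage order is: sample event-count filter → biexponential
transform → cross-sample landmark normalization → doublet removal → gating
→ volume normalization → trait summarization. Each rejection is recorded
in a QC report whose counts add up to the inputs.

* **Event filter.** Samples with fewer than 1000 recorded events are
  rejected; the boundary is strict (exactly 1000 passes).
* **Biexponential transform.** Fluorescence channels are mapped through the
  inverse of $y(x) = a e^{bx} - c e^{-dx} + f$, found by monotone
  root-finding. The defaults $a=c=0.5$, $b=d=1$, $f=0$ make the transform
  exactly `asinh`, which anchors the unit tests analytically. Scatter
  channels are never transformed.
* **Landmark normalization.** Within a panel, the top-`peakNr` density
  modes of each sample (bandwidth `bwFac` × Silverman) are aligned to the
  cross-sample median landmark positions by a strictly increasing
  piecewise-linear warp. This is deliberately simpler than spline-based
  warping: it is easy to reason about, preserves value ranks exactly, and
  is an identity on identical samples. Defaults: `peakNr = 2`,
  `bwFac = 2`.
* **Doublet removal.** Two coincident cells produce roughly the sum of
  their pulse areas at a height near the larger cell's, so the FSC-A/FSC-H
  ratio of a doublet sits near 2 while singlets sit near 1. Events outside
  the band `[0.8, 1.3]` are removed. The original per-panel gating figures
  are replaced by this configurable rule (and by rectangular gate trees for
  population definitions); replicating fifteen manual gating schemes is
  out of scope.
* **Volume normalization.** Cell volume is $3\log_{10}(\text{FSC-A})$
  (the log of the cubed forward-scatter area). The default mode divides
  log10 fluorescence by volume, reading "normalized to cell volume"
  literally; residualization of log10 fluorescence on volume is available
  as an alternative mode because the literal reading is not the only
  defensible one. This choice is configurable precisely because it is a
  judgement call.
* **Trait summaries.** For each (individual, cell type, protein) with at
  least 100 cells, the mean and CV² = s²/mean² of the normalized values are
  recorded. CV² uses the unbiased (n−1) sample variance; with ≥100 cells
  the difference from the n denominator is negligible, but the choice is
  documented and fixed.

# The mean-adjusted variability statistic

CV² is strongly, inversely coupled to mean expression, so raw CV² mostly
re-measures the mean. For each trait, a locally weighted polynomial
regression (tricube weights, degree 2, span 0.75, robustness iterations)
of $\log_{10}\mathrm{CV}^2$ on $\log_{10}\bar{x}$ across individuals
captures the trend; the residuals, standardized to mean 0 and variance 1
(n−1 standard deviation), are the per-individual mean-adjusted variability
η_res. Fitting is on the log–log scale. Each cohort is fitted separately;
pooling cohorts is refused because the mean–CV² relationship is
panel- and instrument-specific. Predictions outside the observed mean
range clamp to the nearest fitted value with a warning.

Two consequences worth knowing: η_res is exactly invariant to rescaling
all CV² values by a constant, and the standardization makes η_res a
*relative* measure — one unit is one standard deviation of residual
variability within that trait and cohort.

# Twin ACE decomposition

Trait covariance between co-twins identifies genetic and environmental
variance shares: the expected genetic relatedness matrix K has 1 for MZ
co-twins, 0.5 for DZ, 0 otherwise; the shared-environment matrix S has 1
within any twin pair. The model covariance is
$\sigma_A^2 K + \sigma_C^2 S + \sigma_E^2 I$, maximized under a Gaussian
likelihood with path-coefficient parametrization $(a, c, e)$ so all
components are non-negative by construction. Because every family has at
most two members, the likelihood factorizes over 2×2 blocks and evaluates
in O(n). Optimization is quasi-Newton from several restarts (tolerance
1e-12 on the objective); a cohort with only MZ or only DZ pairs is refused
because A and C are then not separately identifiable.

Standard errors come from refitting on random 75% subsamples of twin
*pairs* (co-twins are never split). Permutation p-values permute the
zygosity labels *between families*, keeping the pair structure; the
reported p follows the formula $p = 1 - (\#\{test > null\} + 1)/(n+1)$,
which equals $\#\{null \ge test\}/(n+1)$ and can reach exactly zero. This
is slightly anti-conservative relative to the conventional
$(\#\{null \ge test\}+1)/(n+1)$, which is available via
`formula = "standard"`. Whether age should be regressed out first is not
settled; `ace_fit()` takes an optional covariate matrix and the pipeline
leaves it off by default.

The Falconer closed form — $a^2 = 2(r_{MZ} - r_{DZ})$ — is exposed as
`ace_falconer()` and used throughout the tests as an independent moment
oracle. At 500+500 pairs the Monte-Carlo standard deviation of the $a^2$
fraction is about 0.05; tests therefore compare ML against the Falconer
value computed on the *same* draw, and reserve tight truth-recovery
bounds for fixed-seed scenarios.

# Variability-QTL mapping

Variants with cohort MAF < 1% (strict) or Hardy–Weinberg χ²₁ p ≤ 1e-50 are
excluded. GRMs use the standardized-genotype form
$z_{ik} = (g_{ik} - 2p_k)/\sqrt{2p_k(1-p_k)}$, $A = ZZ^\top/m$, with
per-chromosome and leave-one-chromosome-out (LOCO) versions; the weighted
sum of a chromosome's GRM and its complement reconstructs the genome-wide
GRM exactly, which is tested as an identity.

The association model is $y = \alpha + g\gamma + X\beta + Zu + \epsilon$.
Variance components are estimated once per trait under the null by REML —
a single eigendecomposition of the GRM plus a one-dimensional Brent search
over the log variance ratio — and then fixed for all SNPs (the MLMA-style
approximation); $\gamma$ is a generalized-least-squares estimate and
$H_0: \gamma = 0$ is assessed by a t-test with $n - \mathrm{rank}(X) - 1$
degrees of freedom. With an identity relatedness matrix the whole scan
reduces *exactly* to OLS, which serves as the oracle for equivalence
tests. Two numerical notes:

* REML needs an accurate GRM. Each GRM entry carries sampling noise of
  standard deviation $1/\sqrt{m}$; when the number of markers is not large
  relative to the cohort the noise spectrum dilutes the estimated genetic
  fraction and calibration degrades toward OLS. The calibration tests use
  m ≈ 10 n.
* The LMM carries one genetic random effect. A shared-environment
  component in the generative world is family covariance the model does
  not absorb; calibration tests therefore use an additive-only twin world,
  and a C component is expected to produce mild inflation (λ ≈ 1.1 at
  c² = 0.2 in our simulations) — a model limitation, not a bug.

cis windows are 1 Mb centered on the TSS, closed at both ends. The best
nominal p in a window is adjusted by permuting the trait in the whitened
residual space of the null model, fitting a Beta distribution to the
permutation minimum-p sample by maximum likelihood, and evaluating its CDF
at the observed minimum — on independent null SNPs this reproduces the
analytic $1-(1-p)^m$ law, which is the acceptance check. Across traits,
multiplicity is controlled by Benjamini–Hochberg.

Clumping is greedy: candidates at or below the index threshold are sorted
by p (ties by chromosome, position, id); the best unassigned variant
becomes an index and absorbs unassigned variants within 250 kb with
dosage r² > 0.5. The output partitions the candidate set, and a
brute-force greedy reference implementation must agree exactly on random
instances. varSNP annotation uses a fixed geometric rule (gene body;
5 kb strand-aware upstream/downstream bands; otherwise intergenic) in
place of external annotation services, and TSS-proximity enrichment
compares varSNPs against MAF-bin-matched control SNPs in a Fisher 2×2
table. Trans scans can either exclude the trait gene's chromosome or run
genome-wide; both behaviors are supported since the original choice is
not documented.

# Two-sample Mendelian randomization

For each variability-QTL (outcome) and candidate eGene (exposure),
instruments are cis-eQTL records within a 200 kb window centered on the
varSNP, with eQTL p ≤ 1e-5 and a matching cell type, intersected with the
variants present in the outcome statistics. Alleles are harmonized by
sign-flipping swapped pairs; strand-ambiguous palindromic variants (A/T,
C/G) are dropped because input tables are not guaranteed to carry allele
frequencies for orientation.

Estimators: the Wald ratio $\hat\beta = b_y/b_x$ with first-order
delta-method SE; a maximum-likelihood estimator that profiles out the
per-SNP true exposure effects (reducing exactly to the ratio for one
instrument, and to IVW as exposure error vanishes); MR-Egger (weighted
least squares with free intercept, exposure effects oriented
non-negative, requiring ≥ 3 instruments); and Cochran's Q on the Wald
ratios with first-order weights (second-order weights behind a flag).
The pair screen uses the ratio for single-instrument pairs and ML (or
Egger on request) otherwise, applies BH-FDR at 10% across pairs, excludes
empty instrument sets from the denominator, and flags a trans signal as
"explained" when any paired eGene passes.

One simulation-design caveat the tests encode: the Egger slope is only
identified when true instrument strengths vary. A world where every
instrument has the same $\beta_{gx}$ leaves the slope undetermined and
regression dilution leaks into the intercept; Egger simulations therefore
draw strengths from a range.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
stated world of the tests:

* **Genotypes.** Haplotypes follow a first-order Markov copying model
  within LD blocks (copy the previous allele with probability `ld_rho`,
  else redraw at the variant's own frequency); blocks and chromosomes are
  independent; dosages are sums of two haplotypes. With equal allele
  frequencies the stationary adjacent-variant correlation equals
  `ld_rho`, giving clumping tests known LD.
* **Twins.** MZ pairs copy one genome; DZ pairs draw haplotypes from four
  shared parental haplotypes per LD block, so allele sharing is 1/2 in
  expectation. Note that the *across-variant* correlation of two twins'
  raw dosage vectors is inflated by allele-frequency heterogeneity;
  sharing should be measured per variant (or after column centering).
* **Latent traits.** A dispersion-scale trait
  $s_i = \sum_k \gamma_k g_{ik} + A_i + C_f + E_i$ with A shared fully in
  MZ and half in expectation in DZ, C shared within family, E independent,
  and variance fractions equal to `ace_fractions` before SNP effects; a
  mean-scale trait is generated analogously. Ages are uniform on
  [20, 70] years; an optional confounder SNP (a reagent-interaction
  stand-in) shifts the latent mean additively.
* **Cells.** Per singlet, FSC-A is log-normal around the individual's mean
  cell size, FSC-H ≈ FSC-A, and $\log_{10} F \sim N(\mu + \kappa(v -
  \bar v), \sigma)$ couples fluorescence to volume ($\kappa = 0.3$ by
  default). Doublets sum two singlets' areas and fluorescences with
  height near the larger singlet's. The per-cell log-normal law is an
  assumption of this module — the source analyses do not state one — so
  tests built on it establish internal consistency of the pipeline, not
  the distributional fidelity of any real cytometer. Spectral spillover,
  compensation and imputation uncertainty are deliberately not emulated.
* **Causal chains.** $E = \beta_{gx} G + u U + e_1$,
  $V = \beta_{causal} E + u U + \delta G + e_2$, with per-SNP OLS summary
  statistics computed in two disjoint halves of the sample so exposure and
  outcome estimation errors are independent, as the two-sample MR design
  assumes.

What a green test does *not* establish: performance on real FCS files
(ingestion is CSV-canonical; FCS bit-exactness is not promised), behavior
under genotyping error or imputation dosage uncertainty, X-chromosome
traits, and any of the source cohorts' empirical results.

# Reproducibility and budgets

All randomness flows from integer seeds in configuration objects;
identical configurations give byte-identical outputs. The orchestrated
pipeline writes per-stage outputs plus a JSON manifest (config, seed,
stage log). Simulation scales in the test suite are chosen to keep the
full run in well under half an hour on one CPU; where a module-level
property calls for more replicates than that allows, the test says so and
runs a scaled-down count.
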