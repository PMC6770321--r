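---
title: "Models and methods in wheatgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in wheatgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`wheatgp` implements the quantitative-genetics toolchain used in genomic
selection studies of advanced inbred breeding material: marker QC and
VanRaden relationship matrices, REML/GBLUP with one or two genomic kernels,
a single-marker mixed-model GWAS with leave-one-chromosome-out (LOCO)
kinship and genomic control, a Bayesian Power Lasso whole-genome regression,
and a cross-validation engine covering the designs breeders actually use
(leave-one-out, leave-family-out, leave-set-out, k-fold, training-fraction
curves, and split-half genomic-feature protocols). Because the motivating
breeding-line data are proprietary, the package ships a first-class
simulator of such cohorts with ground-truth records, and every statistical
claim in the test suite is made against that synthetic world or against
closed-form oracles.

# The models

## Genomic relationship matrix

Genotypes are coded -1/0/+1 (homozygote / heterozygote / homozygote).
With `M` the code matrix and `P` the matrix whose column *i* holds
`2(p_i - 0.5)` for the frequency `p_i` of the +1-coded allele,

    Z2 = M - P,    G = Z2 Z2' / (2 * sum_i p_i (1 - p_i))

(VanRaden method 1). Missing genotypes are set to exactly 0 in `Z2`, i.e.
imputed at the SNP mean. One reading note: the source formula labels `p_i`
"the MAF", but centering by the literal minor-allele frequency would leave
nonzero column means; the +1-allele frequency is used (the standard VanRaden
convention — the scaling denominator is identical under either reading).

For near-fully-inbred lines (F6) the average diagonal `d(G)` is close to 2,
not 1; nothing in the package hard-codes the diagonal, and the heritability
function takes `d(G)` explicitly:

    h2 = d(G) sigma_g^2 / (d(G) sigma_g^2 + sigma_e^2).

LOCO matrices drop one chromosome's SNPs (frequencies and denominator
recomputed over the retained subset, keeping each G internally consistent);
unmapped SNPs sit on pseudo-chromosome `"UN"`, are retained in every LOCO
matrix, and are scanned against the full-minus-unmapped kinship.
Significance-partitioned pairs (`Gs`, `Gn`) for the genomic feature model
are built the same way. Both QC thresholds are strict inequalities
(MAF > 1%, missingness < 10%), read literally from the editing rule.
A 1e-6 diagonal ridge is applied before any factorization because duplicated
inbred genotypes make G exactly singular.

## REML and BLUP

Variance components are estimated by dense average-information REML with
step halving, an EM fallback, and projection of negative proposals onto the
boundary (a variance that becomes negligible relative to the total is parked
at the floor rather than crawling toward it geometrically — null traits and
tiny "significant" kernels otherwise stall). Convergence requires a relative
log-likelihood change below 1e-8 and a scaled gradient norm below 1e-6, or a
boundary fit; standard errors come from the inverse AI matrix; a
near-singular AI matrix (e.g. `G = I` with one record per line) raises a
non-identifiability warning. The design alternative — an eigendecomposition
fast path for single-kernel fits — was not implemented: at n <= ~650 a dense
iteration costs ~100 ms and cross-validation tractability comes from reusing
variance components across folds instead (the default; `refit_per_fold`
re-estimates them inside every fold).

GEBVs solve the mixed-model equations at the estimated variance ratios via
the equivalent V-inverse form; lines present in a kernel but not phenotyped
get predictions through their kernel covariances, which equals the
conditional-expectation formula `G_vt (G_tt + (se2/sg2) I)^-1 (y_t - X_t b)`
asserted in the tests. Fixed effects are an intercept plus a
treatment-coded breeding-set (year) factor; folds that alias a level (e.g.
leave-set-out training data) drop the aliased column for that fold's fit.

## GWAS

Each SNP is tested by GLS of the phenotype on `[X | w_i]` (codes +1/0/-1,
missing as 0) under `V = sg2 G_loco + se2 I`, with variance components
estimated once per chromosome from the SNP-free LOCO model and held fixed
(EMMAX-style; the source delegates to external software and does not state
per-SNP refitting). The Wald statistic is `(a_i / SE)^2` on 1 df. The
genomic inflation factor is `median(chi2) / qchisq(0.5, 1)` and is applied
unconditionally — also when it is below 1 — matching the unconditional
wording of the correction; `clamp_lambda = TRUE` gives the common
lambda >= 1 convention. The significance threshold is Bonferroni
`alpha / m` over all scanned SNPs.

The per-SNP explained genetic variance is reported as
`100 * 2 p (1-p) a^2 / sigma_g2`. The source table prints the statistic
without a formula; this form reproduces every printed row within rounding
and is consistent on inbred cohorts because both the realized single-SNP
variance (`4p(1-p)a^2`) and the realized total (`d * sigma_g2`, `d ~ 2`)
carry the same factor of two. Allele-combination summary tables use
homozygous classes only and report how many heterozygous/missing lines were
excluded.

## Bayesian Power Lasso

The whole-genome regression `y = Xb + Wu + e` uses dosages `W` coded 0/1/2
(derived from the internal codes as `code + 1` at the model boundary) and an
exponential power prior on each SNP effect,

    p(u_i) = beta * lambda^(1/beta) / (2 Gamma(1/beta)) * exp(-lambda |u_i|^beta).

The source prints the normalizer `lambda/2`, which is exact only at
`beta = 1`; the properly normalized generalized-normal constant is used so
that deviance comparisons across shapes share a footing. Priors on `b` and
`sigma_e2` are flat; `lambda` has a flat prior truncated at 1e6 for
propriety and a conjugate Gamma draw given the effects. At `beta = 1` the
effects update by conjugate scale-mixture Gibbs (Laplace as a
normal-exponential mixture, inverse-Gaussian mixing draws); at `beta < 1`
by per-SNP adaptive Metropolis-within-Gibbs targeting 30-45% acceptance,
with adaptation frozen at the end of burn-in to preserve detailed balance.
SNP effects are initialized at shrunken marginal-regression estimates and
`lambda` consistently with them: starting all effects at exactly zero makes
the conjugate rate draw diverge and, for `beta < 1`, traps the chain at the
sparse attractor (a documented numerical choice, not a statistical one —
burn-in removes any dependence on the start in healthy chains).

Posterior means are accumulated over every post-burn-in cycle; thinned draws
(default every 10th) feed DIC and diagnostics. DIC uses
`pD = Dbar - D(theta_bar)` with the deviance at the posterior means of all
parameters; which parameters the original analysis conditioned on is
unstated, and this all-parameter convention is the package's choice. Shape
selection runs one chain per grid value from the same seed. Single-chain
diagnostics (Geweke z with AR-spectral variance estimates, effective sample
size) are reimplemented in the package; the test suite cross-checks them
against `coda` as an independent oracle. The default grid is
{0.2, 0.4, 0.8, 1.0}; the source's results section once mentions 0.6, which
its methods grid does not contain — the grid is user-configurable and 0.6 is
deliberately not a default.

## Cross-validation

Predictive ability is the Pearson correlation between
fixed-effect-corrected phenotypes and GEBVs of validated lines; bias is the
slope of the regression of corrected phenotypes on GEBVs (expectation 1.0;
both the slope and `slope - 1` are reported since the source prints slopes
while defining bias as the deviation). Phenotypes are corrected once with
the full-data GLS fixed-effect fit and that correction is applied uniformly
across folds; a per-fold correction is available by flag.

"Half-sib family" is ambiguous when parents are reused across crosses;
leave-family-out folds are the connected components of the graph joining
lines that share at least one parent, so no parent ever spans a
training/validation boundary, with an optional size cap that splits
oversized components by full-sib family (with a warning, since the guarantee
is then local). k-fold sampling is stratified by breeding set so training
folds keep the two-set proportions. The training-fraction study follows the
source protocol of leave-one-out *within* a randomly selected fraction of
the lines (so validation counts grow with the fraction — the only reading
under which the replicate SD shrinks toward 90%), computed per replicate by
the closed-form LOO identity `gebv_i = r_i - (V^-1 r)_i / (V^-1)_ii` at
fixed variance components; replicate r uses `seed + r`. The
`make_folds(scheme = "fraction")` plan keeps the plain train/rest split for
use with `run_cv()`. The split-half genomic-feature protocol fixes one
random half for GWAS ranking and evaluates every threshold on the same
other half (re-randomizing per threshold is a plausible alternative the
source leaves unstated); a threshold equal to the SNP count degenerates to
single-kernel GBLUP by construction, which the tests assert to 1e-6.

# The synthetic world

The simulator emulates the population the analysis assumes: 96 crossing
parents (6 shared between two breeding sets of 321 and 314 lines), 159
full-sib families of ~4 lines, single-seed descent to F6 (heterozygosity
~3% of the F1 level), Haldane-model meiosis without interference, and a
set-level effect standing in for G-by-E in a single-location design.
Founder haplotypes are mosaics over a small ancestral pool so LD decays
with map distance; realized founder allele frequencies are clamped into the
configured range by minimal flips.

Choices where the source is silent, made once and not revisited:

* **Map**: SNPs evenly spaced; 21 chromosomes of 160 cM at full scale
  (scaled worlds use 8-10 chromosomes).
* **Family sizes**: as equal as the totals allow (only means are published).
* **Parent pairing**: each set's parents are grouped into crossing clusters
  sized so shared-parent components average ~46 lines (the published
  half-sib mean). Fully random pairing would collapse the shared-parent
  graph into one giant component and make leave-family-out degenerate.
  Parents shared between sets sit in each set's first cluster.
* **Founder pool**: founder haplotypes are mosaics over 8 ancestral
  haplotypes with 80 cM blocks, modeling a narrow elite pedigree. This is
  calibrated against the source's central predictive observation —
  leave-one-out accuracy well above 0.7, approaching the heritability
  ceiling (published r/h ≈ 0.79/0.85) — which a short-LD, wide-pool world
  cannot reproduce (it yields accuracy ≈ 0.6). Matching the published
  ratio exactly would require relatedness so extreme that other stated
  features (within-chromosome LD decay, QTL mapping resolution, the
  effective family count) degrade, so the default sits between (accuracy
  ≈ 0.75-0.78 at 600 lines); unit tests that probe mapping resolution pin
  a short-LD world explicitly.
* **Trait scale**: `genetic_var` is sigma_g^2 on the GBLUP reporting scale,
  so realized var(TBV) = d(G) * genetic_var and published variance
  components can be used verbatim as simulation truth. Residual variance
  follows from the target heritability through the `d(G)`-aware formula, or
  is given directly. Major-QTL effects are kept at face value and the
  polygenic background is rescaled so the total genetic variance hits the
  target exactly.
* **QC exercise**: 1% random missingness by default, no genotyping error.

What a green test does *not* establish: the synthetic world has no
selection during line development, no dominance or epistasis, no
multi-location structure, and its G-by-E proxy is a single additive set
effect — so agreement with the published predictive abilities (computed on
unpublished real data) is out of reach by design. The acceptance suite
therefore checks closed-form statistics against printed inputs exactly, and
the behavioral patterns (CV orderings, genomic-control calibration,
threshold behavior of the feature model) as properties of the synthetic
world at reduced scale: simulations use 600 lines x 3,000 SNPs (REML
recovery, CV orderings), 300 x 10,000 (GWAS calibration), 300 x 2,000
(feature model, 20 seeds), and 25 training-fraction replicates instead of
100. MCMC oracle comparisons run at chain length 20,000-40,000 instead of
the production default 100,000/30,000.

# Numerical notes

* REML floor 1e-10 with reflection; relative-negligibility clamp at 1e-4 of
  the total variance; kernel ridge 1e-6.
* The genomic-control denominator `qchisq(0.5, 1)` is computed, never
  hard-coded.
* Monomorphic-in-sample SNPs are flagged untestable rather than dropped, so
  row counts match the input map.
* All randomness flows from user seeds; identical (design, seed) pairs give
  bit-identical cohorts, and the MCMC uses R's RNG so `set.seed` governs
  the chains.

# Known limitations

Single-trait models only; no pedigree A-matrix path; no multi-chain R-hat
(single-chain Geweke/ESS diagnostics); the Power Lasso stores thinned draws
only when memory allows, and its leave-one-out cross-validation refits a
full chain per fold, which is practical only at reduced scale. The
published head-to-head result — Power Lasso predictions within a couple of
hundredths of GBLUP's — is a full-scale, fully-converged-chain phenomenon:
at test-budget chain lengths the Monte-Carlo noise of the per-fold refits
exceeds that margin, so the suite asserts a coarser same-range property and
the exact comparison is left to production-scale runs.
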