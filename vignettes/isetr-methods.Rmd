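---
title: "Interaction set tests for genotype-context interactions: models and methods"
author: "iSetR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction set tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

iSetR tests whether the joint effect of a *set* of genetic variants on a
quantitative trait differs between categorical contexts — environmental
states, cellular stimuli, or cohort strata such as sex.  For a complete
design with $N$ individuals phenotyped in each of $C$ contexts, the
$N \times C$ trait matrix $Y$ is modelled as

$$ Y = F B + G W + \psi, $$

where $F$ ($N \times K$) holds fixed-effect covariates (intercept, measured
covariates and genotype principal components), $G$ ($N \times S$) the
standardized dosages of the $S$ variants in the region, $W$ ($S \times C$)
their per-context effect sizes, and $\psi$ iid-per-individual residual noise
with trait-context covariance $C_n$ ($C \times C$).  Placing independent
normal priors on the rows of $W$ and marginalizing gives

$$ \mathrm{vec}(Y) \sim \mathcal N\!\left(\mathrm{vec}(F B),\;
   C_s \otimes R_s + C_n \otimes I_N\right), $$

with $R_s = G G^\top / S$ the local realized relatedness matrix and $C_s$
the trait-context covariance of the set component.  Structures of $C_s$
correspond one-to-one to genetic architectures:

* **null** ($C_s = 0$): no set effect;
* **block** ($C_s = a_0 \mathbf{1}\mathbf{1}^\top$): *persistent* effects,
  identical in every context;
* **rank-one** ($C_s = a a^\top$): *rescaling* interactions — all variant
  effects in one context are a common multiple of those in another
  (context-exclusive effects are the multiple-zero special case);
* **full rank** ($C_s = A A^\top$, $A$ lower-triangular): *heterogeneity*
  interactions — the configuration or relative effect sizes of causal
  variants change between contexts.

Three likelihood-ratio tests compare restricted-maximum-likelihood (REML)
fits of these nested structures: **mtSet** (full vs null; any association),
**iSet** (full vs block; any interaction) and **iSet-het** (full vs
rank-one; heterogeneity specifically).  The statistic is
$\mathrm{LLR} = 2(\ell_{\text{full}} - \ell_{\text{reduced}})$, clipped at
zero.  Because the $C_s$ structures are constrained to be positive
semidefinite, a non-trivial fraction of statistics sits exactly on the
boundary at zero; differences below the optimizer's resolution ($10^{-6}$)
are treated as ties and reported as exactly zero, which is what produces
the step at large $p$ in a null QQ plot.

For stratified cohorts — every individual phenotyped in exactly one
context, e.g. males versus females — the same model applies with observed
covariance $V_{ij} = C_s[c_i, c_j] R_s[ij] + \delta_{ij} C_n[c_i, c_i]$.
Off-diagonal entries of $C_n$ never enter this likelihood (no individual is
observed twice), so the stratified $C_n$ is restricted to its diagonal.

# Inference

Fixed effects are profiled out by generalized least squares at every
candidate covariance, so the optimization runs only over the free
covariance parameters.  Unconstrained parametrizations keep every candidate
PSD by construction: $a_0 = c^2$ for the block structure, a free vector $a$
for rank one, free lower-triangular factors for the full $C_s$, and a
lower-triangular factor with exponentiated diagonal for $C_n$ (strictly
positive definite).  L-BFGS-B minimizes the negative restricted
log-likelihood from a moment-based start (fractions of the empirical trait
covariance of the covariate-adjusted phenotypes) plus seeded perturbed
restarts (three by default; bootstrap refits use two).  Convergence uses a
projected-gradient tolerance of $10^{-5}$ with at most 500 evaluations per
restart.

Evaluations are cheap by design.  For complete designs, a one-off thin SVD
of $G/\sqrt S$ yields the non-zero eigenvalues $d_j$ of $R_s$ and the
rotated data $U_1^\top Y$, $U_1^\top F$; whitening by the Cholesky factor
of $C_n$ and rotating contexts by the eigenvectors of
$L_n^{-1} C_s L_n^{-\top}$ renders the covariance diagonal with entries
$1 + s_i d_j$.  Coordinates in the null space of $R_s$ have unit weight and
enter only through Gram-matrix corrections, so a single evaluation costs
$O(S C^2 + S K^2 C^2)$ — independent of $N$ after the precomputation, which
is itself $O(N S^2)$ (when $S \ge N$ the factorization is bounded by the
sample-space decomposition instead).  Gradients for the complete design are
analytic, derived from the standard REML trace identities evaluated in the
same rotated representation.  For the stratified design the covariance is
written as a rank-$\le CS$ update of a diagonal, and Woodbury identities
reduce every term to per-context Gram matrices precomputed once per region;
its gradient is a central finite difference of this (very cheap, smooth)
objective — an implementation choice made because stratified fits are a
small share of total compute, while the complete-design path carries the
large calibration and bootstrap workloads.

A dense reference implementation (`denseOracle`) builds the full
$(NC) \times (NC)$ (or $N \times N$) covariance explicitly and evaluates
the identical objective by direct factorization; the test suite asserts
agreement with the efficient paths to below $10^{-8}$ across layouts and
covariance structures.

# Empirical p-values

Permutation tests are not well defined for interaction hypotheses, so null
distributions are generated parametrically: for each region, $J$ bootstrap
replicates are drawn from the *fitted reduced model* (block for iSet,
rank-one for iSet-het) and the full and reduced models are refitted on each
replicate; mtSet uses $J$ permutations of the genotype rows relative to the
phenotypes (preserving the trait-context covariance of $Y$) instead.  The
$J \cdot T$ null statistics are pooled across all $T$ tested regions and

$$ p = \frac{1 + \#\{\mathrm{LLR}_{\text{null}} \ge \mathrm{LLR}_{\text{obs}}\}}
            {1 + J T}, $$

with ties counted as exceedances (conservative).  The $+1$ smoothing keeps
$p$ strictly positive; the attainable floor is $1/(JT + 1)$, so a
Bonferroni correction across the $T$ regions can at best reach a
family-wise error rate of about $1/J$ (with the default $J = 30$, about
0.03) — reaching stricter genome-wide thresholds requires more bootstraps.
Benjamini-Hochberg q-values are computed per test across regions.

Every region derives its random streams from (global seed, region index),
so chunked execution of a genome scan is byte-identical to serial
execution, and null draws are reproducible row by row in the archive TSV.

# The synthetic-data framework

The simulators exist to measure calibration and power under controlled
architectures; their defaults *are* the standard study conditions used
throughout the tests.

**Genotypes.** Cohort haplotypes are mosaics of founder haplotypes with
per-base-pair geometric switch points (exponential inter-switch distances,
rate `recombRate`).  Founder haplotypes are drawn by thresholding a latent
AR(1) Gaussian process at per-site frequency quantiles (frequencies
$\sim U(\text{mafMin}, 0.5)$), so the founder pool itself carries
haplotype-block structure with correlation decaying as
$\exp(-d/\texttt{ldScale})$.  This second ingredient matters: with
site-independent founders, pairwise $r^2$ is capped near
$1/n_{\text{founders}}$, far below human levels, and region kernels barely
tag sparse causal variants.  The defaults — 16 founders, switch rate
$10^{-5}$/bp, `ldScale` 50 kb, 120 variant draws per 30 kb, MAF $\ge$ 2% —
were chosen once to match realistic 30-kb European-ancestry LD summaries:
mean pairwise $r^2 \approx 0.27$, adjacent-variant $r^2 \approx 0.55$, and
an effective number of independent tests around a third of the variant
count.  An LD-free binomial mode and a two-subpopulation mode (shared
latent founders thresholded at diverged frequencies; divergence 0 recovers
a homogeneous cohort) complete the family.  What the mosaic does *not*
emulate: coalescent-exact allele-frequency spectra, recombination hotspots,
rare variants, or real population demography — so passing tests demonstrate
statistical behaviour under realistic LD, not performance on any particular
real cohort.

**Phenotypes.** Each context's trait is the sum of a regional genetic
component, a population-structure component, $K = 10$ hidden confounding
factors and iid Gaussian noise.  The variance budget per context is:
region $v_r$ (default 2%); of the residual $1 - v_r$, a fraction
$\beta = 0.5$ from hidden factors; of what remains, a structure fraction
(default 0.2 — the available parameter table does not fix this split, so it
is a package choice exposed as `structureFraction`) and the rest iid noise.
Structure and hidden components are built from shared plus context-specific
ingredients so their cross-context correlation is $\alpha = 0.6$.
Components are rescaled empirically — divide by the realized standard
deviation, multiply by the target — so the variance ledger is exact per
replicate rather than in expectation, which makes the calibration targets
sharply testable.  The regional component's scaling is
architecture-dependent: persistent and rescaling architectures use one
factor shared across contexts (mean per-context fraction $v_r$), which
preserves the fold change in explained variance implied by the
proportionality factor $\eta$ ($\eta = 1$: no interaction; $\eta = 0$:
context-exclusive; $\eta < 0$: opposite effects); the heterogeneity
architecture scales each context's effect column to exactly $v_r$, since
column scaling leaves the effect correlation untouched.  Heterogeneity
draws context-specific causal sets and rejection-samples effect draws until
the realized cross-context correlation of the regional effects lands within
$\pm 0.05$ of the target (or within an explicit band), capped at 10,000
attempts.

Misspecification modes for robustness checks: a single causal variant
(violating the polygenic prior), an epistatic product term of a random
variant pair (added persistently, scaled to $v_r$), and outliers of $\pm 8$
added to a random 0.1% of trait entries.  The three-locus illustration
places persistent, rescaling ($\eta = -0.5$) and heterogeneity loci of
30 kb far apart (negligible inter-locus LD), each explaining 5% of total
phenotypic variance.

# Variance decomposition

Fitting the block, rank-one and full structures to one region gives
explained set variances $\bar{C_s[c,c]}/\widehat{\mathrm{var}}(y_c)$
(region standardization normalizes the mean diagonal of $R_s$ to 1, so
$C_s[c,c]$ is directly the variance scale of the set component).  The
decomposition attributes incrementally along the nested hierarchy:
persistent = block's explained variance; rescaling = the block→rank-one
increment; heterogeneity = the rank-one→full increment; increments are
floored at zero so the fractions stay interpretable and sum exactly to the
reported total.  Two caveats are deliberate: the REML fits are nested in
*likelihood*, not in the diagonal of $\hat C_s$, so the diagonal-based
explained variance can dip by $O(10^{-3})$ between structures; and the
incremental attribution is one of several defensible decompositions — it
matches the observable behaviour that a persistent model captures
positively-correlated GxC but none of the variance under negative
rescaling, while the full model remains unbiased for the total.

# Baselines and annotation

The single-variant comparator tests, per variant, a persistent effect plus
a variant-by-context interaction (1 df for two contexts) by generalized
least squares with the residual covariance $C_n \otimes I$ fixed at its
no-genetics REML estimate; region-level significance is the minimum
interaction p-value corrected by Bonferroni or by an eigenvalue-based
effective-test count (smallest $k$ capturing 99.5% of the variant
correlation variance — an approximation in the spirit of published
effective-test estimators, not a reimplementation of any one of them).
Regions with marginally significant per-context lead variants are
classified by lead-variant LD: distinct leads ($r^2 < 0.2$), shared lead
($r^2 > 0.8$; sub-labelled by context-specific secondary associations and
effect-direction concordance), and an unresolved intermediate band.  The
baseline heterogeneity score is $1 - r^2$ between per-context leads when
both are significant, else 0.  Enrichment of opposite-direction pairs among
heterogeneity calls uses the sample odds ratio and a one-sided Fisher exact
p-value.

# Numerical choices and problem sizes

Tolerances: oracle agreement $10^{-8}$; gradient tolerance $10^{-5}$;
LLR tie threshold $10^{-6}$; PSD jitter $10^{-6}$–$10^{-8}$ where Cholesky
factors of empirical matrices are needed; heterogeneity correlation
tolerance 0.05.  Degenerate inputs fail loudly: regions with no variant
surviving the MAF filter, constant traits under quantile normalization,
rank-deficient covariates, singular BLUP covariances.

The shipped test suite runs the statistical property checks at sizes chosen
as a deliberate compromise between resolution and turnaround: type-I error
on 500 persistent-only regions ($N = 1000$, $J = 30$) against the exact
binomial 99% band around $\alpha = 0.05$; iSet-het power on 200
heterogeneity replicates ($N = 1000$, $J = 30$, uncorrelated effects);
rescaling calibrations on 150 regions with $J = 20$; simulator variance
targets on 500 regions / 100 illustration replicates.  Larger designs
tighten the bands but change nothing qualitatively.

# Known limitations

Continuous contexts require discretization; intermediate designs (complete
with missing phenotypes) are not supported; the genome-wide random-effect
background adjustment for closely related individuals is out of scope (the
implemented path is principal-component adjustment, adequate for nominally
unrelated cohorts); heterogeneity testing on stratified cohorts is
statistically valid under the model but vulnerable to differential allele
frequencies or genotyping accuracy between strata, so it is not part of the
recommended stratified workflow.  Set resolution is bounded by the window:
power is best when the causal region matches the testing region, and the
heterogeneity test degrades fastest as windows grow.
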