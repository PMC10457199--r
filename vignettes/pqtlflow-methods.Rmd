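---
title: "Models and methods behind pqtlflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pqtlflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlflow)
```

`pqtlflow` chains six analyses that together take cohort-level GWAS
summary statistics for circulating proteins to causal statements about
disease: meta-analysis, locus definition, conditional analysis,
colocalization, Mendelian randomization (MR), and mediator
prioritization at trans loci. This vignette explains the statistical
model behind each stage, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## The data model

Every stage exchanges a plain `data.frame` of per-variant association
records: alleles, effect-allele frequency $f$, additive effect $b$ (in
SD units of an inverse-rank-normalized trait for quantitative traits,
log-odds for case-control), its standard error, a two-sided p-value
and sample size $N$. Two conventions run through the package:

* **p-values are carried in $-\log_{10}$ space** (`mlog10p`, computed
  from the z-score via the normal log-survival function). Strong pQTLs
  reach $P \sim 10^{-300}$ and beyond, where the p-value itself
  underflows double precision; every threshold comparison uses the
  log-scale column, and `p_from_z()` uses the survival-function
  formulation so $|z| \le 37$ stays representable.
* **All two-sided p-values use the normal approximation**, matching
  the convention of summary-statistic meta-analysis tools; no
  t-distributions anywhere.

Allele harmonization flips $b \to -b$, $f \to 1-f$ when a record's
alleles are swapped relative to the target orientation. For
strand-ambiguous pairs (A/T, C/G) both orientations are
sequence-compatible, so `harmonize()` compares the allele frequency
against the target's under both readings and only accepts when the two
discrepancies differ by more than 0.1 (the `freq_gap` default);
otherwise the record is `"unmatchable"`. This conservative policy
trades a little data for protection against silent sign flips — the
worst failure mode a meta-analysis can have. The policy is
configurable because multi-cohort pipelines differ in how they handle
these variants.

When a resource distributes only z-scores and frequencies, effect
sizes are reconstructed as
$$b = z/d, \qquad \mathrm{s.e.} = 1/d, \qquad
  d = \sqrt{2f(1-f)\,(z^2 + N)},$$
which preserves $b/\mathrm{s.e.} = z$ exactly (`z_to_beta_se()`).

## Meta-analysis and its filters

`meta_fixed()` is the standard fixed-effects inverse-variance pooling;
`meta_analyse()` applies it across variants after harmonizing all
cohorts to a common orientation. Heterogeneity is summarized by
Cochran's $Q$ and $I^2 = \max(0,(Q-(k-1))/Q)\cdot 100$ ($I^2 = 0$ when
$k = 1$ or $Q = 0$).

The verdict logic in `apply_meta_filters()` encodes how a multi-cohort
proteomic study guards against spurious signals driven by one cohort's
technical artifacts:

| filter | default | action |
|---|---|---|
| presence | ≥ 3 cohorts **and** ≥ 3,500 participants | `excluded` |
| significance | $P \le 5\times10^{-10}$ | `not_significant` above |
| consistency | if $I^2 > 30$: ≥ 3 cohorts with $p<0.05$, direction matching the pooled effect | `filtered_heterogeneous` otherwise |

The significance threshold is itself derived: Bonferroni correction of
the conventional genome-wide $5\times10^{-8}$ for roughly 100 protein
GWAS (`study_wide_threshold()`). Boundary conventions are deliberate
and tested: p-thresholds compare with $\le$, $I^2$ with strict $>$,
and QC floors (MAF ≥ 0.001, info ≥ 0.3) are inclusive; Hardy–Weinberg
uses strict $P > 10^{-6}$. Cohorts missing a variant contribute `?` to
the direction string and never count toward the consistency rule. The
presence floor is evaluated after cohort QC, so a variant QC-dropped
in some cohorts must still clear 3 cohorts / 3,500 participants with
what remains. A genomic-control $\lambda$ is computed per protein for
diagnostics but never used to rescale — rescaling is a modeling
decision the pipeline does not take.

## Locus definition and conditional analysis

`define_regions()` expands each significant variant by ±1 Mb and
merges transitively until no two intervals overlap, treating
exactly-touching closed intervals as overlapping (the open boundary
convention at exact 2 Mb adjacency; merging slightly more is the safer
default for sentinel bookkeeping). Intervals are clipped at position 1
on the left and unclipped on the right (synthetic coordinates carry no
chromosome lengths). Sentinels are chosen by lowest p, then largest
$|z|$, then smallest position, so outputs are deterministic under
ties. A signal is *cis* when its sentinel lies within 1 Mb of the TSS
of the protein's encoding gene on the same chromosome (inclusive),
*trans* otherwise.

`conditional_stepwise()` re-derives multiple-regression estimates from
marginal statistics and an LD correlation matrix $R$, the standard
summary-statistic approximation: with diagonal scalings
$D_j = 2f_j(1-f_j)N_j$ (the implied $X^\top X$ diagonal for a
variance-1 trait), the joint solve on a selected set $S$ is
$\hat b_S = A^{-1} (D_S b_S)$ with $A = \sqrt{D_S} R_{SS} \sqrt{D_S}$,
and the conditional effect of a candidate $j$ is
$$b_{c,j} = b_j - \sum_{k\in S} r_{jk}\sqrt{D_k/D_j}\;\hat b_k, \qquad
  \mathrm{s.e.}_{c,j} = \sqrt{\frac{\sigma^2}{D_j\,(1 - q_j)}}, \quad
  q_j = r_{jS} R_{SS}^{-1} r_{Sj}.$$
The residual variance is fixed at $\sigma^2 = 1$: the trait is
inverse-rank normalized and individual loci explain a few percent of
it at most, so the unit-variance approximation is accurate, slightly
conservative, and makes the orthogonal-LD case collapse *exactly* to
the marginal per-variant tests (a tested identity). Selection starts
at the sentinel, admits the most significant conditional candidate
while $p_c \le 5\times10^{-10}$, skips candidates with $r^2 > 0.9$
against the selected set (collinearity cap) or MAF < 1% (sentinels
exempt), and ridge-stabilizes ($10^{-6}$ on the diagonal, with a
warning) if an LD submatrix is numerically singular. Selected signals
are finally pruned to pairwise $r^2 \le 0.1$ by ascending p with
sentinels forced in. Note what the procedure can and cannot promise:
at $r^2 \approx 0.95$ a pure-LD shadow of a causal variant is
statistically interchangeable with it, so the guarantee is that no
*extra* signal is reported, not that the causal member of the pair is
the one selected.

Variance explained uses
$\mathrm{PVE} = \sum_i \chi_i^2/(\chi_i^2 + N_i - 2)$ over sentinels,
each term in $[0,1)$; a total ≥ 1 triggers a warning since it signals
a non-independent sentinel set.

## Colocalization

`log_abf()` is the Wakefield approximate Bayes factor
$\tfrac12[\log(1-r) + r z^2]$ with $r = W/(V+W)$, prior effect SD
$\sqrt W = 0.15$ for quantitative traits and $0.2$ (log-odds) for
case-control — the delegated defaults of the coloc framework, recorded
in every result object since only the hypothesis priors, not the
effect priors, are usually reported. `coloc_pair()` combines
per-variant ABFs for two traits into posteriors over the five
single-causal-variant hypotheses with priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, summing in log space
(log-sum-exp) so that $|z|$ up to 200 stays finite; PP4 ≥ 0.8 is
called colocalized. Variants missing in either trait are dropped by
intersection — no imputation of missing summary statistics.

`pwcoco()` extends this to multi-signal loci: run the stepwise
conditional analysis on each trait (entry $5\times10^{-8}$ here, the
genome-wide threshold, since disease GWAS rarely reach the pQTL
study-wide level), condition each signal on the trait's other signals
via `conditioned_sumstats()`, and colocalize every cross-trait signal
pair plus the unconditioned pair, reporting the matrix and its
maximum PP4. With one signal per trait this reduces identically to
`coloc_pair()`. Conditioning on the empty set is the identity;
conditioned variants themselves are zeroed. A conditional-solve
failure falls back to the unconditioned pair with a warning rather
than silently dropping the locus. Caps on the number of variants
entering stepwise selection and on the LD window are left unbounded —
at the scales this package targets they never bind. Three-way
colocalization questions are answered by requiring pairwise PP4 ≥ 0.8
for all pairs rather than by a dedicated multi-trait model.

## Mendelian randomization

Exposures are per-SD protein levels, outcomes log-odds of disease, so
the causal estimate exponentiates to an odds ratio per SD of protein.
`select_instruments()` takes the cis region (encoding gene ± 1 Mb),
keeps variants with exposure $P \le 5\times10^{-8}$ and an
allele-frequency mismatch ≤ 0.4 against the LD reference, greedily
clumps to $r^2 \le 0.1$ by ascending p, and demands ≥ 3 survivors —
otherwise the protein–disease pair is `"insufficient"` and no estimate
is produced. Proteins encoded in the HLA region should be excluded
upstream; its LD is too complex for this instrument model.

`gsmr_estimate()` combines Wald ratios
$\hat\beta_i = b_{zy,i}/b_{zx,i}$, with variances
$v_i = (se_{zy,i}^2 + \hat\beta_i^2 se_{zx,i}^2)/b_{zx,i}^2$, by
generalized least squares under the instrument correlation
$V_{ij} = r_{ij}\sqrt{v_i v_j}$. With uncorrelated instruments this is
identically inverse-variance weighting of the ratios (a tested 1e-10
equivalence). `heidi_outlier()` tests each instrument's ratio against
the most precise (top exposure-p) instrument's,
$d_i = \hat\beta_i - \hat\beta_{ref}$ with delta-method variance
including the LD-induced covariance, and removes $p(d_i) < 0.05$; the
reference is never removable.

One calibration property deserves honesty. The HEIDI deviation test
itself is exact (measured removal rate 4.6% at the 5% threshold,
uniform deviation p-values), but *any* trim-then-re-estimate scheme at
a 5% threshold is mildly anti-conservative, because the kept set is
selected for agreement with the noisy reference ratio: with valid
instruments the post-trimming causal test rejects a true null at
≈ 0.075–0.08 instead of 0.05. This is intrinsic to the procedure — it
persists with independent instruments and exactly known variances —
and is not an implementation artifact. The package therefore
calibrates and tests the GSMR estimator itself (type-I ≈ 0.045–0.048
over 2,000 null pairs; 3-SE recovery of a planted $\theta = 0.3$ in
99.6% of replicates), reports the with-HEIDI rate alongside it in the
acceptance output, and relies on the downstream FDR (BH across all
protein–disease models jointly, q < 0.01) and robustness filters to
absorb the difference. The robustness audit demands a convincing
disease signal at the locus (min $P \le 10^{-4}$), tight LD between
the exposure sentinel and the best disease variant ($r^2 > 0.8$), and
colocalization support (max PP4 ≥ 0.8); each failure is recorded
separately in the verdict.

## Mediator prioritization at trans loci

A trans-pQTL says some local gene product regulates a distant
protein; `prioritize_mediators()` ranks the candidates. Local genes
are those with TSS within ±500 kb of the sentinel (inclusive), ordered
by distance with gene-id tie-breaks. Four evidence classes are
combined by simple counting into a tier: (1) among the 3 nearest
genes; (2) cis-eQTL support — the sentinel is the gene's local eQTL
sentinel, in $r^2 \ge 0.8$ with it, or in a supplied credible set;
(3) protein–protein interaction with the trans-affected protein, from
a user-supplied interaction table; (4) annotation-term overlap:
a two-sided Fisher exact test (hypergeometric convention: total
probability of tables no more likely than observed) on the 2×2
classification of the locus background — the union of all local
genes' terms — by membership in the local gene's and the target
protein's term sets, Bonferroni-corrected by the number of local
genes, significant at adjusted p < 0.05. Ties in tier break by
adjusted p, then distance. Counting classes rather than weighting
them keeps the ranking transparent; any weighting would be arbitrary
without training data, and the manual literature-review step that
real analyses append is inherently out of scope.

## The synthetic-data generator

`simulate_ld_panel()` builds blocks of variants with allelic
correlation $r_{ij} = \rho^{|i-j|}$ (AR(1)) within blocks and
independence across blocks — blocks are spaced 10 Mb apart so they
never merge into one locus. Defaults emulate the study design the
pipeline targets: 11 cohorts of unequal sizes summing to ≈ 14,800
participants, an eQTL dataset of 31,684, a disease GWAS of 10,000
cases / 30,000 controls, MAFs uniform on the configured range,
$\rho = 0.8$.

Summary statistics are drawn directly from sampling theory: for a
standardized trait and standardized genotypes the marginal z-vector of
a cohort is $\mathcal N(\sqrt N\, R\,\beta^{std},\, R)$, so one
multivariate-normal draw per cohort replaces individual-level
simulation — orders of magnitude faster, and exact for the quantities
downstream stages consume. A slow path
(`simulate_individual_gwas()`, explicit dosages and per-variant
regressions) cross-validates the fast path in the tests. Between-cohort
heterogeneity adds $\mathcal N(0,\tau^2)$ to the true effect per
cohort; the tests verify that mean $I^2$ rises monotonically in
$\tau$. Disease GWAS are generated on the log-odds scale with
effective sample size $N\phi(1-\phi)$; under vertical pleiotropy the
disease effect at each protein causal variant is
$\theta\,\beta_{protein}$, and the `ld_confounded` mode instead places
an independent disease effect on a neighbour at configurable $r^2$ —
the scenario HEIDI and conditional colocalization must flag. Each
cohort consumes its own seed stream, so cohorts are independent and
every output is a deterministic function of the config.

What the generator does *not* emulate — and hence what passing tests
do not certify about real data: realistic human LD (long-range
structure, variable block sizes), population stratification and
relatedness, genotype-level artifacts (imputation error is summarized
by an `info` column, not modeled), assay batch effects beyond a
scalar heterogeneity SD, sample overlap between exposure and outcome
GWAS, and case-control ascertainment beyond the effective-N
approximation. The pipeline's behavior under those forces must be
argued from the design of the filters, not from these simulations.

## Problem sizes and numerical choices

The test and acceptance workloads use panel sizes chosen to make
every statistical assertion sharp at desk scale: 10⁶ null
variant-tests for the zero-false-positive check of the significance
verdict; 2,000 null exposure–outcome pairs for MR type-I; 300
replicates for 3-SE recovery checks (nominal coverage 99.7%, so a
≥ 99% assertion has comfortable margin); 100 replicates for
architecture-recovery, HEIDI-removal and mediator-ranking rates;
conditional-analysis recovery is exercised at per-signal marginal
$z \approx 8.5$–9, the regime where a two-signal architecture is
identifiable at the study-wide threshold. MR calibration uses 13
planted cis instruments, the instrument count of the motivating
use case.

Numerical safeguards: LD matrices are symmetrized and
ridge-stabilized ($10^{-8}$ on the Cholesky; $10^{-6}$ with a warning
on singular conditional solves); log-sum-exp throughout
colocalization; `max(1-q, 10^{-6})` guards conditional variances;
monomorphic dosage columns yield zero correlation rather than NA.
Degenerate inputs are contracts, not crashes: empty significant sets
give empty region lists, zero shared variants is an error naming the
harmonization step, an empty term background skips the Fisher test
with a reason, and `"insufficient"` instruments is a value, not an
error.

## Known limitations

* The conditional analysis is the standard summary-statistic
  approximation, not individual-level regression; it inherits the
  usual sensitivity to LD-reference mismatch (not modeled here, where
  the reference is exact by construction).
* Colocalization assumes at most one causal variant per conditioned
  signal; fine-mapping-based alternatives are out of scope.
* The MR estimator trims outliers before re-estimating; see the
  calibration discussion above. MR-Egger, weighted-median and
  multivariable variants are deliberately not implemented.
* Mediator ranking is evidence counting, not a calibrated posterior.
* The CLI wrapper runs the whole chain regardless of the subcommand —
  at the package's scale every stage is cheap, and stage boundaries
  exist for testing and reuse, not scheduling.
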