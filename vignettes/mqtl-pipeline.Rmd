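---
title: "Methods: mQTL mapping, colocalization, and SMR/HEIDI in mqtlpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mQTL mapping, colocalization, and SMR/HEIDI in mqtlpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlpipe)
```

# Scope and model

`mqtlpipe` analyses the joint architecture of common genetic variation and
DNA methylation, and propagates mQTL signals into two downstream questions:
do neighbouring CpGs share a causal variant (colocalization), and do CpGs
share genetic signals with complex traits or gene expression (SMR with the
HEIDI heterogeneity filter)? This vignette is the package's methodological
record: the models, every tunable that matters, the numerical choices, and
what the synthetic validation does and does not establish.

## The association scan

For each (variant, CpG) pair the model is an additive linear regression of
the methylation beta value on the dosage (0/1/2 copies of the effect
allele) plus covariates: age (years), sex, six blood cell-composition
estimates (proportions), two binary batch indicators, and ten genotype
principal components. The implementation residualizes both the trait matrix
and the dosage matrix on the covariates once, then forms all pairwise
statistics with blocked cross-products — the standard fast-scan identity.
Algebraic equivalence with per-pair OLS (including the explicit
$n - k - 2$ degrees of freedom, $k$ = number of covariates) is a tested
property, not an assumption; variants with missing calls fall back to a
per-variant complete-case path in which the covariate projection is
recomputed on the retained samples, matching casewise-deletion OLS exactly.

Methylation is analysed on the beta scale, untransformed, so that
`effect_pp = 100 * b` is exactly "percentage points of methylation per
allele". The alternative (M-values or rank transforms) would decouple the
reported effect from that interpretable unit; calibration of the scan under
the null is instead demonstrated directly on simulated data.

Key thresholds (all named arguments or config keys, with their conventional
values): save threshold $10^{-8}$ (strict `<`); genome-wide Bonferroni
$5\times10^{-8}/\#\text{CpGs}$; "discovery" eligibility $10^{-10}$ for
colocalization and SMR instruments; cis window 500,000 bp, boundary
inclusive (a pair exactly 500 kb apart is cis, 500,001 bp is trans).

## Clumping

Per CpG, greedy index selection: repeatedly take the most significant
unassigned variant with $p \le$ `p1` as index and absorb unassigned
variants with $p \le$ `p2`, within ±`window_kb` of the index position and
$r^2 \ge$ `r2_cut` with the index (defaults 1e-8, 1e-8, 250 kb, 0.1). LD is
computed from dosages in the analysis panel itself — the same panel that
produced the associations, so no external reference is needed. p-value ties
are broken by (chromosome, position, ID), making output fully
deterministic. Each CpG's results are clumped independently.

## Colocalization

Per-SNP evidence is the Wakefield log approximate Bayes factor
$\tfrac12\log(1-r) + \tfrac12 r z^2$, $r = w^2/(w^2+\mathrm{var}(b))$, with
prior effect SD $w = 0.15$ appropriate for a quantitative trait analysed on
a standardized scale. The five-hypothesis posterior uses priors
$p_1 = p_2 = 10^{-4}$ and $p_{12} = 10^{-5}$ (the method's conventional
defaults, deliberately left untouched). All sums run in log space; the H3
cross-term $\sum_{i \ne j}$ is computed stably as the log-difference
between the full product term and the matched-index term, and for windows
of up to six SNPs the log-space path is tested against a naive linear-space
enumeration to $10^{-10}$. Windows with fewer than two SNPs are an error
(H3 is undefined). Pairs are CpGs on one chromosome within 250 kb of each
other, both with at least one discovery-threshold mQTL; each pair's SNP set
is the intersection of the two ±500 kb windows, which requires the scan to
be rerun unthresholded for eligible probes (the pipeline does this
automatically). Three nested labels are emitted rather than a single call:
`shared_region` (PP3+PP4 > 0.99), `shared_variant` (additionally
PP4/PP3 > 1), `convincing` (additionally PP4/PP3 > 5).

A note on an invariance subtlety: rescaling both traits' `b` and `se`
jointly changes the absolute ABFs (the prior SD is fixed), but leaves the
PP4/PP3 evidence ratio exactly invariant — the test suite asserts the
ratio form. Traits should be entered on a standardized scale when absolute
PP0–PP2 values matter.

## SMR and HEIDI

The exposure-outcome effect at the top instrument is the Wald ratio
$b_{xy} = b_{zy}/b_{zx}$, tested with
$T = z_{zx}^2 z_{zy}^2/(z_{zx}^2+z_{zy}^2) \sim \chi^2_1$. The top
instrument is the smallest exposure p among SNPs present in both studies
after allele harmonization (sign flips on swapped allele pairs;
strand-ambiguous A/T and C/G pairs dropped and counted). Alternates for
HEIDI require exposure $p < 1.57\times10^{-3}$ (equivalently $z^2 > 10$),
$r^2$ with the top in $[0.05, 0.9]$, pairwise pruning at $r^2 > 0.9$
keeping the smaller exposure p, and a cap of 20 — the published defaults of
the summary-data MR methodology, all exposed as arguments, with a minimum
of 3 alternates before HEIDI is attempted.

HEIDI's statistic sums standardized squared deviations
$d_i = b_{xy}(i) - b_{xy}(\mathrm{top})$. First-order variances and
LD-driven covariances use signed dosage correlations from the exposure
panel; cross-study covariance terms vanish because exposure and outcome
cohorts share no samples (the generator enforces this by construction).
The null distribution of the correlated chi-square sum is evaluated by
Monte Carlo under the caller's RNG stream (default 50,000 draws in the
API, scaled per use), with numerical inversion of the characteristic
function of the eigenvalue-weighted mixture (Imhof's integral) as the
analytic cross-check; the two agree within Monte-Carlo error in tests.
Covariance matrices that drift off the PSD cone are projected by
eigenvalue clipping and flagged. Degenerate sets (alternates statistically
identical to the top) yield $T = 0$, $p = 1$ exactly.

Design gates: the trait design requires a discovery-threshold
($10^{-10}$) cis mQTL and corrects $\alpha = 0.05$ for the number of
exposures tested; the expression design additionally requires an eQTL with
$p < 5\times10^{-8}$ and a common variant within 500 kb of both probes,
correcting for the number of (CpG, expression-probe) pairs. "Pleiotropic"
means passing both the corrected SMR threshold and HEIDI $p > 0.05$; the
package deliberately does not claim causality or direction.

## Enrichment statistics

Probes are annotated to a gene when inside the body or ≤1,500 bp upstream
of the TSS (strand-aware; boundary inclusive), and to island context as
island / shore (≤2,000 bp) / shelf (2,000–4,000 bp, inclusive at 4,000) /
open sea, boundaries resolving toward the nearer-to-feature class.
Distribution shifts use Pearson chi-square ($k-1$ df); 2×2 enrichment uses
Fisher's exact p with the cross-product odds ratio as the point estimate
(the used convention is documented rather than the conditional MLE);
direction concordance uses the exact sign test computed in log space, so
p-values like $10^{-149}$ are exact and anything below the double floor is
still reported through `log10_p`; location shifts use Mann-Whitney with
exact enumeration (tie-safe) when the smaller group has ≤8 observations
and the tie-corrected normal approximation otherwise.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with a truth ledger for every planted signal.

* **Genotypes.** Haplotypes follow an allele-copying Markov chain within
  LD blocks: allele $j$ copies allele $j-1$ with probability $\rho$
  (default 0.9), else is a fresh Bernoulli draw at the block's frequency
  (uniform in [0.05, 0.5] per block). Population correlation between
  variants $k$ apart is therefore exactly $\rho^k$ — chosen so that
  clumping, colocalization and HEIDI consume LD with a known law. Blocks
  (default 40 × 50 variants, 5 kb spacing) are independent and spread over
  two chromosomes.
* **Methylation.** Beta values: baseline U(0.2, 0.8) plus
  $(b/100)\times$dosage with $b = \pm|N(3.46, 3.01)|$ percentage points —
  the empirical effect-size scale reported for significant blood mQTLs,
  acknowledged to be a winner's-curse-inflated description of significant
  hits rather than the true architecture, and therefore a config choice.
  70% of CpGs carry an effect (`effect_fraction`); 8% of effects are trans
  (another chromosome), matching the ~92% cis fraction observed in blood.
  Values are clamped to [0, 1] and clamping rates logged per probe.
* **Covariates.** Age, sex, six Dirichlet cell proportions made
  deliberately dependent on genotype PC1 (so covariate adjustment is
  load-bearing), with small estimation noise so the six columns are
  jointly identifiable next to an intercept; two batches; ten genotype PCs.
* **Outcome cohorts.** GWAS (default n = 20,000) and eQTL (n = 5,000)
  summary statistics come from explicitly simulated independent cohorts
  drawn from the same LD law — never from analytic formulas — so the
  two-sample assumption and the `.ma` pathway are exercised end to end.
  Pleiotropic loci (default 10, $b_{xy} = 0.5$) are restricted to CpGs
  with |effect| ≥ 2.5 pp and to one locus per LD block: without the
  per-block restriction, planted effects of opposite sign within one block
  cancel in the marginal GWAS signal and the planted Wald ratio is no
  longer identified — the ledger must stay recoverable by the stage it
  targets.
* **Determinism.** Every dataset derives from `seed` through fixed
  substream offsets (documented in `?sim_config`), so a config fully
  determines all outputs; the pipeline manifest records output hashes and
  reproduces exactly under a seed.

Default cohort size is 1,000 — the scale of the population methylation
cohorts this class of analysis runs on, and large enough that distal HEIDI
instruments retain adequate strength for the first-order variance
approximations.

What the generator does **not** emulate: realistic human LD maps and
recombination hotspots, array probe chemistry and technical artifacts,
cell-type-specific methylation signals, rare variants, relatedness, or
population stratification beyond a planted PC-composition correlation.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to every failure mode of
real array data — probe-level QC of real data remains upstream of this
package's inputs.

# Numerical and edge-case choices

* Filter order is fixed and logged: missingness → MAF → HWE →
  genotype-group count → INFO; removals are attributed to the first
  failing filter and filtering is idempotent. MAF uses non-missing calls;
  HWE and group counts use rounded hard calls.
* HWE defaults to the chi-square test (the convention behind the usual
  PLINK invocation at these thresholds); the conditional exact test is
  available via `method = "exact"`.
* PCA outliers: |PC1| or |PC2| beyond 2 SD; components are recomputed
  after removal, mirroring the two-pass covariate-PC convention.
* Scan ties at the save threshold: strict `<`. Output ordering: probe,
  then p, ties by (chromosome, position, variant ID). Tables are written
  in scientific notation with 6 significant digits, making write→read
  round-trips bit-identical on the written representation.
* Effect alleles are explicit everywhere (`a1` = counted allele); whether
  mQTL effect alleles were minor, reference or dosage alleles is not
  derivable from printed conventions, so outputs always carry both allele
  labels and sign conventions are auditable. Allele-flip equivariance
  (dosage $d \to 2-d$ flips $b$, preserves $|t|$ and $p$) is a tested
  invariant.
* Monte-Carlo HEIDI p-values use $(1 + \#\{T_0 \ge T\})/(1 + B)$, so a
  reported p is never exactly 0 and the degenerate homogeneous case is
  exactly 1.

# Problem sizes used in validation

The test suite and acceptance script run at deliberately modest scale: the
scan-vs-OLS check uses 100 random pairs from a 250-sample, 160-variant,
40-CpG study; null calibration uses 10,000 scan tests and 2,000 SMR
replicates; HEIDI size and SMR recovery use 100 single-block replicates
(exposure n = 2,000; GWAS n = 10,000–20,000); colocalization recovery uses
50 shared-causal and 50 distinct-causal replicates (n = 1,000, 30-SNP
block); the end-to-end pipeline runs the default 1,000-sample, 2,000-variant,
300-CpG configuration. These sizes were chosen as the smallest at which
the targeted properties have stable power; all are arguments, and scale up
unchanged.

# Known limitations

* Single-causal-variant assumptions: colocalization considers at most one
  causal variant per trait per window, and SMR cannot distinguish one
  shared variant from two in near-perfect LD — associations are reported
  as pleiotropic, never causal.
* HEIDI accepts, rather than rejects, a null of homogeneity; with weak
  instruments ($z_{zx} \lesssim 4$) the first-order Wald-ratio variances
  degrade and the test can over-reject, which is why instrument gates
  exist and why small exposure cohorts yield conservative pleiotropy
  counts.
* Conditional/stepwise signal selection (COJO-style), multi-SNP SMR,
  MR-Egger-type sensitivity analyses, kinship-adjusted association and
  fine-mapping outputs are out of scope.
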