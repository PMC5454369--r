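---
title: "Mapping molecular QTLs with molqtl: models, permutation schemes and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping molecular QTLs with molqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molqtl)
```

## The problem

A molecular QTL (molQTL) is a genetic variant associated with a molecular
phenotype — gene or exon expression, a chromatin mark, methylation. Given a
dosage matrix for thousands to millions of variants and a quantification
matrix for thousands of phenotypes over the same samples, the statistical
tasks are: (i) find, for each phenotype, its best associated variant in a
local *cis* window and attach a multiple-testing-adjusted p-value to it;
(ii) do the same when phenotypes come in groups (exons of a gene, peaks of
a chromatin module); (iii) dissect loci into multiple independent signals;
(iv) scan genome-wide for distal (*trans*) associations with a usable FDR;
(v) relate discovered QTLs to functional annotations; and (vi) catch
sample mislabelling before any of this is attempted.

## The elementary test

All mapping modes share one primitive: the Pearson correlation $r$ between
a dosage vector and a phenotype vector, both previously residualized
against the covariates (and the phenotype optionally rank-normalized).
The two-sided p-value is that of $t = r\sqrt{\mathrm{df}/(1-r^2)}$ with
$\mathrm{df} = n - 2 - K$ for $K$ covariates. Residualizing both sides
first makes this numerically identical to the $t$-test of the variant's
coefficient in the full multiple regression (a property the test suite
asserts against an independent normal-equations fit), while reducing every
permutation scan to a standardized matrix cross-product — the reason the
permutation schemes are affordable. The df correction for covariates is
applied both in nominal p-values and inside the permutation null (the same
residualized data generate both). Missing dosages are mean-imputed per
variant at test time; the stored MAF is computed on non-missing values.
Reported p-values are floored at 1e-300. Phenotypes are rank-normalized by
default ($\Phi^{-1}((\mathrm{rank}-0.5)/n)$, mid-ranks for ties); the
approximate trans scheme relies on this, and a single default avoids
mode-dependent behaviour. The cis window (default ±1 Mb, inclusive at both
ends) is anchored on the phenotype's BED start coordinate translated to
the 1-based system, regardless of strand; anchoring on the transcription
start for minus-strand phenotypes is deliberately not the default, because
the window definition must be fixed and documented rather than
annotation-dependent, and the window is symmetric anyway.

## Cis permutations and the beta approximation

For one phenotype with $L$ cis variants, the nominal best p-value is not
interpretable without correction: the effective number of tests depends on
local LD and allele frequencies, so Bonferroni over $L$ is too harsh. The
permutation scheme draws from the null by permuting the phenotype $R$
times (default 1000), re-scanning all variants each time and keeping the
per-permutation minimum p-value. A two-parameter beta distribution is then
fitted to the $R$ minima and the adjusted p-value is the fitted CDF at the
observed best nominal p. The second shape parameter is interpretable as
the effective number of independent tests (for $L$ independent uniform
tests the minimum is exactly Beta(1, $L$); the test suite checks that the
fitted shape grows linearly in $L$ with slope 1 for independent variants
and drops below $L$ under LD). The empirical p-value
$(1 + \#\{\text{minima} \le p_{\min}\})/(1 + R)$ is reported alongside; the
beta fit exists to interpolate beyond the $1/(R+1)$ floor.

Fitting is by maximum likelihood: method-of-moments initialization, then
Newton–Raphson on the two-parameter beta log-likelihood with step halving,
converging when the log-likelihood moves by less than 1e-8 (at most 100
iterations). On failure the moment estimate is kept and flagged; the
conditional-mapping threshold machinery then falls back to empirical
quantiles of the stored minima instead of the beta quantile function.

**Groups.** A group of $M$ member phenotypes (e.g. exons of one gene) is
scanned over all $M \times L$ pairs; each member keeps its own window and
the union is tested. Permutations reorder all members with the *same*
index sequence, which leaves the within-group correlation matrix exactly
unchanged and breaks only the genotype–phenotype link, so the fitted null
correctly prices both the number of variants and the number and
correlation of members. With $M = 1$ the group scheme reduces bit-for-bit
to the single-phenotype scheme (asserted at fixed seed). Two collapse-based
alternatives are provided: `grouped = "pca1"` replaces the group by its
first principal component across scaled members (sign fixed against the
member mean), and `grouped = "mean"` by the member mean (equivalent to a
summed quantification up to scale). On simulations where the signal lives
in one of eight correlated members, the discovery ordering at 5% FDR is
extended scheme ≥ mean ≥ PCA collapse — the collapses dilute a
member-specific signal, and PC1 aligns with the shared latent factor
rather than the signal-carrying member.

**FDR across phenotypes.** Storey–Tibshirani q-values on the adjusted
p-values: $\hat\pi_0(\lambda)$ on the grid $0.05, 0.10, \ldots, 0.95$,
smoothed with a df-3 cubic smoothing spline and read off at the largest
$\lambda$. Below 100 phenotypes the grid is unstable and $\pi_0$ is forced
to 1 (Benjamini–Hochberg behaviour, also available explicitly).

**Reproducibility.** Every analysis unit (phenotype or group) draws its
permutations from a stream keyed by (global seed, unit id), so results are
independent of how phenotypes are chunked or parallelized.

## Conditional mapping

A single reported QTL per phenotype understates loci with several
independent regulatory variants. The conditional pass has three steps.
*Initialization*: from the q-values of the permutation pass, the
adjusted-p significance cutoff at the target FDR is the midpoint between
the largest significant and smallest non-significant adjusted p; feeding
it through each phenotype's fitted beta *quantile* function converts it
into a per-phenotype nominal threshold that automatically reflects the
effective number of local tests. *Forward*: repeatedly take the best
remaining variant; while its p-value beats the threshold, record it as an
independent signal and residualize its dosages out of the phenotype
(candidate dosages are also projected out of the remaining variants so
perfect proxies cannot re-enter); stop otherwise, capping at 10 signals.
*Backward*: with candidates $Q_1 \ldots Q_R$, every other variant $v$ is
tested $R$ times in the joint model with $Q_i$ replaced by $v$ (full QR
fits, since the candidates sit in the model simultaneously); $v$ is
assigned to the signal minimizing its p-value when that p-value passes
the threshold. Rank-deficient substitutions (e.g. $v$ collinear with a
fixed candidate) are skipped. The same transformed phenotype used in the
permutation pass is used throughout, so forward p-values are consistent
with the thresholds derived from it.

The per-phenotype threshold is only meaningful inside a cohort: analysing
one phenotype alone leaves the midpoint rule with nothing non-significant
to bracket against and the resulting loose threshold inflates the signal
count. The recovery simulations therefore embed signal loci in a cohort
with null phenotypes.

## Trans mapping

The nominal pass tests every phenotype × variant pair except
same-chromosome pairs within the exclusion radius (default 5 Mb);
inter-chromosomal pairs are always tested. Detailed rows are only emitted
below a reporting threshold (default 1e-5); all tested p-values are
accumulated in a fixed-width histogram of $-\log_{10} p$ (bin 0.1, range
0–20, overflow in the last bin), so rows plus bins conserve the test count
and calibrated QQ plots remain possible without storing millions of rows.
Genotypes stream against all phenotypes at once as matrix blocks.

*Full permutation scheme*: all phenotypes are co-permuted with one index
sequence (their correlation structure is preserved) and the genome-wide
scan repeated, $B = 100$ times by default. For the $i$-th smallest nominal
p, $\mathrm{FDR}_i = m_i/(iB)$ where $m_i$ counts permuted p-values at or
below it (ties count as smaller — the conservative reading). The counting
is performed on the $|r|$ scale, which is equivalent at fixed df and avoids
evaluating the $t$ tail for every permuted pair. A step-up (monotone)
version of the FDR column defines the discovery set.

*Approximate scheme*: assuming independent, normalized phenotypes, the
null distribution of the genome-wide minimum p-value is shared across
phenotypes, so it can be built cheaply by permuting one randomly chosen
phenotype per draw (uniformly, with replacement; 1000 draws by default)
and keeping the minimum over variants. A beta fit to these minima adjusts
every nominal p-value for the number of variants; Storey q-values on the
per-phenotype best adjusted p correct for the number of phenotypes, and
the adjusted-p cutoff at the target FDR is back-propagated to flag all
genome-wide-significant pairs. On simulated data with planted effects the
5% FDR discovery sets of the two schemes coincide almost exactly (Jaccard
≥ 0.8 asserted over 20 replicates). Confounders the full tool chain would
worry about (cross-mappability, homology, mis-annotation) are out of
scope; the distance exclusion is the only guard.

## Annotations

`annotation_density` counts, in bins (default 1 kb) spanning a window
(default ±1 Mb) around QTL positions, how many annotation intervals
overlap each bin (half-open intervals; a variant at 1-based position $p$
overlaps BED interval $[s,e)$ iff $s < p \le e$). `annotation_enrichment`
asks whether QTLs fall inside annotations more often than expected *given*
the distribution of annotations around phenotypes: each of the $X$
phenotypes owns the list of annotations within the window of its anchor,
stored as anchor-relative offsets; the observed frequency $f_{obs}$ is the
fraction of the $Y$ significant QTLs landing in their own phenotype's
list; permuting whole lists across phenotypes (uniform label permutation,
fixed points allowed; lists re-anchored on the receiving phenotype) and
recounting gives the expected frequency $f_{exp}$. Storing offsets is what
makes a list meaningful on another phenotype at a different genomic
position. Observed and aggregate expected counts are compared by Fisher's
exact test on $[[\mathrm{obs}, Y-\mathrm{obs}],[\sum \mathrm{exp}, BY-\sum
\mathrm{exp}]]$ — counts are aggregated over all $B$ permutations rather
than averaged so the table stays integer. A QTL overlapping several
annotations counts once. Known limitation: the exact test treats the $BY$
permuted draws as independent observations while they re-use the same QTL
offsets, and its p-value is discrete; under a null placement the p-value
distribution is therefore somewhat conservative, noticeably so when $Y$ is
small (tens). Calibration checks in the test suite use $Y$ in the
hundreds, where the granularity is fine enough for approximate uniformity.

## Sample QC

`match_samples` scores every (sequence sample, genotype sample) pair from
per-site allele read counts at sites with coverage ≥ 10 (default): a
heterozygous site is concordant when both alleles are seen and the minor
read fraction is ≥ `hom_tol`; a homozygous site when the matching-allele
read fraction is ≥ 1 − `hom_tol` (`hom_tol` = 0.1 by default — a binomial
error allowance; the underlying studies give no number). Het and hom rates
are reported separately: mislabelling collapses het concordance toward the
random-sharing level, while contamination preferentially depresses the
homozygous rate. The argmax over genotype samples recovers the true
pairing exactly in the bundled simulations (20 samples, 500 sites, 30×).
`pca_covariates` provides the standard PCA (SVD of centred, optionally
scaled data, deterministic sign convention) used to derive expression or
genotype stratification covariates.

## The simulator

`simulation_spec`/`simulate_dataset` generate genotypes as Binomial(2,
MAF) draws, optionally with AR(1) LD: two latent Gaussian haplotype chains
are thresholded at the MAF quantile, with the latent correlation
calibrated per adjacent pair (bivariate-normal orthant probability) so
that the *genotype* correlation matches the requested $\rho$. Because the
correlation of two thresholded binaries is bounded when their MAFs differ,
the generator clamps at the achievable maximum; LD-dependent tests
therefore use MAF bands where the target is feasible (e.g. $\rho = 0.5$
with MAF in [0.2, 0.4]). Phenotypes are sums of planted effects on
standardized dosages, a group-shared latent factor (members of a group
correlate at $s^2/(s^2+1)$ for latent sd $s$; $s = 3$ gives the 0.9 used
in group calibration tests), optional global confounding factors, and
Gaussian noise (sd 1). Allele counts are Poisson-coverage binomial draws
from a sample's own (or a designated other) genotype with a 1% read error.
Everything is reproducible from (spec, seed), and a truth table of planted
effects accompanies each dataset.

What the simulator does not emulate: realistic recombination / coalescent
LD beyond AR(1), allele-frequency spectra, read-mapping artefacts, batch
structure beyond linear factors, or count-distributed (non-Gaussian)
quantifications. Passing tests demonstrate the statistical machinery is
correct and calibrated under these idealized conditions, not that any
particular biological dataset will behave identically.

## Problem sizes and numerical choices

The test suite runs the calibration checks at desk scale, chosen as the
smallest sizes at which the asserted distributional properties are
informative: 500 null phenotypes (L = 20, n = 100, R = 1000) for
beta-vs-empirical agreement and uniformity; 500 groups of M = 8 at member
correlation 0.9 for the grouped null; 20 replicate datasets of 25 groups
for the power ordering; ~108 loci per k ∈ {1,2,3} (n = 500, L = 40,
AR(1) ρ = 0.75) for conditional recovery; 20 datasets of 100 phenotypes ×
10,000 variants (5 planted trans effects, B = 100 vs 1000 approximate
draws) for scheme agreement; 500 replicate enrichment datasets (X = 800,
Y = 400, B = 100); 20 samples × 500 sites at 30× for matching. Beta fits
require at least 50 permutations; q-value estimation switches to π0 = 1
below 100 p-values; thresholds and tie-breaks (distance to anchor, then
variant id) are deterministic so fixed seeds give bit-identical output.
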