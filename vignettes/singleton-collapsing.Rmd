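---
title: "Singleton collapsing for gene-based rare-variant association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Singleton collapsing for gene-based rare-variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supervar)
```

## The problem and the model

Rare variants (minor allele frequency below 1%) are individually almost
untestable in small case-control sequencing cohorts: a variant seen in one
or two carriers cannot reach significance in any exact test, whatever its
effect. `supervar` implements a gene-based analysis built around one
aggregation device, the **supervariant**. For a gene with singleton
variants $j = 1, \dots, s$ (a *singleton* is a variant whose minor allele
is observed exactly once in the whole cohort, i.e. a single heterozygote),
each sample $i$ receives the binary carrier indicator

$$X_i = \begin{cases} 1 & \text{if } x_{ij} = 1 \text{ for any singleton } j,\\
0 & \text{otherwise,}\end{cases}$$

where $x_{ij}$ is the allele dosage. The singletons of a gene, useless one
at a time, act collectively through $X$: if rare causal alleles are
scattered over a gene, case status should predict carriage of *some*
singleton. The supervariant is characterised with Fisher's exact test,
conditional-MLE odds ratio and exact confidence interval, and the gene as
a whole is tested with three permutation-based statistics.

Two properties of this construction matter for validity. Singleton status
is determined over all samples jointly — cases and controls together,
before any phenotype information is used — so the feature definition is
permutation-invariant and the permutation null is exact. And a lone
*homozygote* (minor-allele count 2) is deliberately not a singleton; the
definition is on allele count, not carrier count.

## The three gene-level statistics

Each gene's feature matrix $F$ holds the dosages of its non-singleton rare
variants plus the binary supervariant column (collapsing can be disabled
to compare against the uncollapsed analysis). With binary phenotype $y$,
case fraction $p_0$, per-feature total minor-allele counts $n_i$ and case
counts $y_i$:

* **SSU / linear-kernel score test**: $U = F^\top(y - \bar y)$,
  $S = U^\top U$ with flat weights. This is the quality-unweighted
  multivariate score association test, equivalent to the linear-kernel
  SKAT statistic.
* **C-alpha**: $T = \sum_i (y_i - n_i p_0)^2 - n_i p_0 (1 - p_0)$, a
  homogeneity test of the case/control split of each feature's allele
  copies against a common binomial. For binary $y$,
  $y_i = (F^\top y)_i$, so $T$ differs from $S$ only by a
  permutation-invariant constant: under a shared permutation stream the
  two always produce identical p-values. They are both reported because
  their observed statistics live on different scales and the equivalence
  holds only for the flat-weight binary-trait case.
* **CMC**: features are grouped into minor-allele-count bins (default:
  count $= 1$, i.e. the supervariant's class, and count $\ge 2$); the
  per-sample bin-carrier indicators are compared between cases and
  controls with Hotelling's $T^2$ in the pooled-covariance metric, using
  the Moore–Penrose pseudo-inverse because singleton-heavy indicator
  matrices are routinely rank-deficient. The bin edges are configurable
  (`cmc_breaks`).

Significance of all three is assessed by label permutation only — no
asymptotic approximations. The permutation p is $b/B$, where $b$ counts
permutations whose statistic meets or exceeds the observed one (ties count
against significance, with a $10^{-9}$ relative tolerance so that float
recomputation cannot split exact ties); $b = 0$ is displayed as "< 1/B".
The conservative $(b+1)/(B+1)$ convention is available as an option. All
methods of one gene and stage share one permutation stream, which makes
their p-values directly comparable and halves the cost of the scan.

Because $10^6$ permutations for every gene is wasteful, the scan is
two-step: every gene is screened at $B_1 = 1000$ permutations, and genes
with an estimated p below `alpha_promote` (default 0.001) for at least one
method are re-tested at $B_2 = 10^6$ for all methods. A screen threshold
quoted as "p < 0.001" can be read either as $b = 0$ of 1000 or as
$b/B < 0.001$; the two coincide at $B_1 = 1000$, and the implementation
uses `p < alpha_promote` so the plan generalises to other $B_1$. When
$B_1 = B_2$ the scan collapses to single-stage testing. Genome-wide
significance is Bonferroni, $\alpha/\#\text{genes}$, with the denominator
configurable (a genome-wide scan of roughly 10,000 genes at
$\alpha = 0.05$ gives the conventional $5 \times 10^{-6}$ gene-based
threshold).

## Preprocessing and region stratification

The ingestion path applies, in order: a known-site exclusion list
(canonical `chrom:pos:ref:alt` keys or rsIDs — a stand-in for a dbSNP
build, supplied by the user rather than bundled), a MAF filter, and a
missing-rate filter. Both thresholds remove only *strictly* larger values:
MAF exactly 1% and missingness exactly 5% are retained. MAF is folded
(minor allele, whichever it is) and computed over non-missing genotypes
before imputation; remaining missing genotypes are then resampled uniformly
from the variant's non-missing values. Variants are grouped into genes by
transcript span, `[txStart, txEnd]` inclusive at both ends and 1-based;
variants inside no transcript are dropped, and a variant inside two
overlapping transcripts joins both gene sets (so overlapping-gene tests
are not independent — relevant when choosing the multiple-testing
denominator). Gene *length* is reported as `txEnd - txStart`, the
convention of transcript-table arithmetic.

For region stratification each in-gene position maps to exactly one of
CDS (exonic and inside the coding interval), UTR (exonic outside it, or
any exon of a non-coding transcript), or INTRON. Region subsets inherit
the gene-level singleton list rather than recomputing it — a singleton of
the gene remains a singleton of its region — so region singleton counts
partition the gene's. Strand is read and reported but plays no role in
the three-way classification.

## Population-stratification check

Ancestry confounds a case-control comparison when subpopulations differ
in both disease rate and allele frequencies. The check follows standard
practice: principal components are computed from a random sample of
common variants (no missing genotypes, MAF strictly above 0.1; requesting
more variants than qualify takes all with a warning), with per-variant
z-scaling — the simpler of the two common standardisations, exposed as
the place to change if the allele-frequency-variance scaling is wanted —
and a deterministic sign convention (largest-magnitude loading positive).
The supervariant is then re-tested by logistic regression of case status
on the carrier indicator plus the top $k = 10$ score vectors, with
per-coefficient Wald tests (chosen over likelihood-ratio tests because
statements like "the components were not significant" are
per-coefficient statements). Perfect or quasi-perfect separation is
detected from diverging ML estimates and handled by a Firth
bias-reduced refit, flagged in the output.

## What the synthetic cohorts emulate

The generator's defaults are the study conditions of the motivating
design throughout the validation suites: 64 cases and 39 controls
(n = 103), genes carrying tens to hundreds of rare variants of which
roughly a third are singletons (the canonical signal shape is 380
variants with 135 singletons spread over a 93.5 kb, 26-exon,
intron-dominated transcript with expected region proportions 14:6:360),
and a carrier-level effect expressed retrospectively: controls carry at
least one signal-gene singleton with probability $q_0$
(`control_carrier_rate`, default 0.44) and cases with the $q_1$ solving
$q_1/(1-q_1) = \mathrm{OR} \cdot q_0/(1-q_0)$ (default OR 8.8). The
default $q_0$ is the control carrier fraction of the unique 2x2 table
that `reconstruct_table()` recovers from the published Fisher summaries
at these margins; with it, simulated signal cohorts land in the same
operating regime as the motivating analysis. Retrospective sampling is
used rather than a prospective logistic model because the target
quantity is a carrier odds ratio — exactly what the Fisher analysis
estimates. Which carrier receives which singleton is uniform among the
drawn carriers, each carrier receiving at least one.

A consequence of the cohort size worth stating: with $n = 103$, MAF
$\le 1\%$ caps the minor-allele count at 2, so every non-singleton rare
variant is a doubleton, placed as two heterozygotes in distinct samples.
Larger simulated cohorts draw counts uniformly in
$\{2, \dots, \lfloor 2n \cdot \mathrm{MAF}_{max} \rfloor\}$.

In confounded mode, each sample belongs to subpopulation A or B (cases
and controls with different probabilities), common background variants
follow a Balding–Nichols model at a configurable $F_{st}$, and each
*gene* is assigned an ancestral subpopulation toward which all its
rare-variant carriers are skewed by the divergence parameter. The
gene-level (rather than variant-level) assignment is a deliberate design
choice: a symmetric variant-level skew averages out across a gene's
singletons and leaves the supervariant unconfounded, producing nothing
for the adjustment to correct, whereas recent rare variation is in
reality strongly ancestry-private and shared along haplotype
backgrounds, which clusters by locus. Signal genes stay unconfounded so
effect and confounding can be composed independently.

The generator deliberately does **not** emulate: linkage disequilibrium
between variants, relatedness or pedigree structure, sequencing error or
genotype-quality variation, multi-allelic sites, indels, or sex
chromosomes. Passing calibration and power suites on these cohorts
therefore demonstrates correctness of the statistical machinery under
the stated sampling model, not robustness to those real-data features;
in particular the type-I-error results say nothing about cryptic
relatedness, which must be removed upstream.

## Numerical choices

* Exact 2x2 inference (p by summing hypergeometric probabilities no
  larger than the observed table's, conditional-MLE odds ratio, CI by
  inverting one-sided tests at 0.025 per side) is delegated to
  `stats::fisher.test`; the test suite verifies it against an
  independent noncentral-hypergeometric enumeration. One caveat
  uncovered there: the reference solver locates very large upper CI
  bounds on the reciprocal-odds scale to about $10^{-4}$ absolute, so
  bounds in the thousands carry a few percent of solver noise — far
  inside any printed precision, but visible to an oracle.
* `reconstruct_table()` enumerates all tables with the given margins and
  matches the published p at its own printed number of significant
  digits and the CI at two decimals.
* Degenerate inputs are flagged, not silently dropped: genes with zero
  singletons yield an untestable all-zero supervariant; zero-variance
  features are removed with a message; empty region subsets are
  reported untestable; zero-margin 2x2 tables are an error.
* All randomness flows through one integer seed via deterministic
  per-purpose child seeds (cohort, imputation, each gene x stage, PCA
  selection), so stages are individually reproducible and a scan is
  byte-identical across reruns.

## Problem sizes in the validation suites

The calibration and power suites are sized to run comfortably on one
CPU: 500 null genes at 200 permutations for type-I error and
uniformity, 1,000 replicate cohorts for odds-ratio recovery and CI
coverage, 20 replicate signal cohorts (380 variants, 135 singletons)
for the collapsing-boost comparison, 120 confounded and 25 structure-free
replicates for the stratification check, and exhaustive 2x2 enumeration
to margins of 20 for p-values (10 for the full OR/CI inversion, plus a
400-table sample beyond). These sizes give binomial 99% bands tight
enough to detect miscalibration of a few percentage points.

## Known limitations

* The CMC bin edges of the original combined-multivariate-and-collapsing
  proposal are not uniquely standard; the default two-bin layout
  (singletons vs other rare) matches the collapsing-centred analysis
  here, and other layouts should be supplied via `cmc_breaks` when
  comparing against other software.
* With collapsing enabled the three tests consume the
  supervariant-augmented feature matrix; the uncollapsed alternative is
  one flag away and is the right baseline when quantifying the boost.
* Permutation at $B = 10^6$ for many promoted genes is the dominant
  cost; the engine vectorises SSU and C-alpha but evaluates Hotelling's
  $T^2$ per permutation, so CMC dominates the runtime of deep
  confirmation stages.
* The exact tests condition on both margins; their conservatism at
  these sample sizes is visible in the null suites as rejection rates
  slightly below nominal.
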