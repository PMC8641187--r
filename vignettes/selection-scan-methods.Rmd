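---
title: "Methods: selection-signature scanning with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-signature scanning with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Livestock breeds under intensive artificial selection carry localized
genomic footprints: allele-frequency differentiation against unselected
populations (elevated FST) and depleted nucleotide diversity around the
selected site. `sweepscan` implements a chip-data scan for such
footprints in multi-breed diploid SNP panels — for example, comparing
unmanaged indigenous sheep breeds against commercial meat and dairy
breeds — together with the population-structure diagnostics one reports
alongside such a scan (runs of homozygosity, LD decay, a neighbour-joining
tree), and a forward simulator that provides cohorts with *known* selected
loci so the whole pipeline can be validated against ground truth.

## The statistics

### Locus FST from mean squares

For `s` subpopulations with per-locus diploid sample sizes $n_i$ and alt
frequencies $p_i$:

$$\bar p = \frac{\sum_i n_i p_i}{\sum_i n_i},\qquad
MSP = \frac{1}{s-1}\sum_i n_i (p_i-\bar p)^2,\qquad
MSG = \frac{1}{(\sum_i n_i)-1}\sum_i n_i p_i (1-p_i),$$

$$F_{ST} = \frac{MSP - MSG}{MSP + (n_c-1)\,MSG},$$

with $n_c$ the arithmetic mean of the $n_i$. Two deliberate knobs exist
because the literature is not uniform here: `nc = "wc"` substitutes the
variance-corrected
$n_c = (\sum n_i - \sum n_i^2/\sum n_i)/(s-1)$, and
`msg_denom = "sum_minus_1"` substitutes $\sum_i(n_i-1)$ for the MSG
denominator. The defaults follow the arithmetic-mean / total-minus-one
reading; with balanced samples the variants differ negligibly.

Two analytic facts the tests pin down:

* a fixed difference gives $F_{ST}=1$; identical frequencies give the
  negative value $-1/(n_c-1)$, which is retained (not clamped) by default;
* the *no-divergence sampling limit* of this estimator is **not**
  $-1/(n_c-1)$: with both subpopulations drawn iid from a common $p$,
  $E[MSP]=p(1-p)/2$ and $E[MSG]=p(1-p)$ exactly, so the mean locus value
  converges to $-1/(2n_c-1)$. The simulator test asserts this derived
  value.

Windows (default 100 kb, step 50 kb, half-open `[start, start+window)`
starting at position 1) aggregate loci either as the ratio of sums
$\sum(MSP-MSG)/\sum(MSP+(n_c-1)MSG)$ (`weighted`, the default, the
convention of windowed-FST tools) or as the arithmetic mean of defined
locus values (`mean`). Windows without an informative locus are omitted.

Group comparisons default to two *pooled* subpopulations (s = 2): the
source data do not say whether breeds were pooled or entered as s > 2
subpopulations, so both are supported (`pool = FALSE` uses breeds
separately); pooling is the default because the two Manhattan-plot
comparisons (indigenous vs meat, indigenous vs milk) are naturally
two-population contrasts.

### Windowed diversity and the delta-pi scan

Per-site diversity is the proportion of pairwise differences among the
`n` non-missing chromosomes, $\pi = a(n-a)/\binom{n}{2}$ for alt count
$a$ — algebraically $2\hat p(1-\hat p)\,n/(n-1)$, unbiased for
$2p(1-p)$. Window diversity (default 50 kb window, 25 kb step) is the sum
of site values divided by the *window length in bp*, the chip-data
convention in which unassayed positions count as invariant. Windows with
zero SNPs are retained at 0 by default (`drop_empty` flips this); their
treatment only matters for the quantile of the difference scan.

The sweep scan is the per-window difference
$\Delta\pi = \pi_{\mathrm{reference}} - \pi_{\mathrm{focal}}$, where the
*focal* group is the one screened for diversity loss; windows in the top
1% are reported. The caller chooses the orientation: screening commercial
breeds for artificial-selection sweeps subtracts commercial π from
indigenous π; screening the indigenous group reverses it.

### Empirical outliers

Outlier tiers are empirical: the threshold is the k-th largest window
value with $k=\lceil f\,n\rceil$ for top-fraction $f$ (ties at the
threshold all included), so "top 1%" of 100 distinct values is exactly
the maximum. A stated significance cut-off of P ≤ 0.05 on window FST is
implemented as the top-5% empirical tier — with no permutation scheme
specified, the empirical quantile is the only self-consistent reading.

### QC and pruning

A locus survives iff pooled MAF > 0.01 (strict, as printed), call rate ≥
0.90 (boundary kept), and HWE exact p > 1e-5. The HWE test is the full
enumeration of heterozygote counts conditional on allele counts, summing
the probabilities of configurations no more probable than the observed
one. Pooled testing is the default (matching the named tool run without
family information), but **pooled HWE in a structured cohort measures the
Wahlund effect, not genotyping error**: with the simulator's eight
drifted breeds it would discard most strongly differentiated loci —
including every sweep. The pipeline therefore uses
`hwe_mode = "per_population"` on simulated cohorts (a locus fails if any
single breed violates HWE), and this choice is surfaced in the config
rather than buried.

LD pruning reimplements sliding-window pairwise pruning (window 100 SNPs,
step 50, r² > 0.1): r² is the squared Pearson correlation of dosage
vectors on pairwise-complete samples; within a window the worse-MAF
member of the worst pair is removed (tie: later position), making the
procedure fully deterministic. The pruned set feeds *only* the
relatedness stages (tree); FST/π scans use the full post-QC set, since
pruning exists to de-cluster relatedness estimates.

### ROH, LD decay, tree

ROH detection uses a maximal-run definition: per sample and chromosome,
maximal consecutive-SNP stretches of homozygous calls tolerating
`max_het` heterozygotes (default 0) and `max_missing` missing calls
(default 1), reported if span ≥ 1000 kb (the figure-level definition;
the methods-level 100 kb is available by argument — the two stated
values conflict and the figure defines the reported quantity) and
SNP count ≥ `min_snps`. This replaces the scanning-window heuristic of
the original tool, whose window-hit parameters are unstated; for clean
runs the two coincide, and the tolerances are exposed under the same
names. Run extension is greedy left-to-right and runs are trimmed to
start and end on homozygous calls.

LD decay averages r² in seven distance classes with upper edges 2.5, 5,
10, 20, 40, 80, 160 kb (left-open, right-closed bins), with seeded
uniform subsampling per class to keep the pair count tractable.

The tree stage computes allele-sharing (IBS) distances — the source
names only "pairwise distances", so the allele-sharing distance is an
assumption, stated here: sample level $d = \mathrm{mean}|x-y|/2$;
population level the same on alt-frequency vectors — and neighbour
joining with two determinism conventions: Q-matrix ties break to the
smallest index pair, and negative branch lengths are clamped to zero
with the deficit moved to the sibling edge (disable with
`clamp_negative = FALSE`). On additive matrices the tree reproduces the
input exactly (property-tested against an exhaustive least-squares
oracle). Bootstrap support resamples loci with replacement (default
1000 replicates) and reports the percentage of replicates containing
each internal bipartition.

### Annotation and enrichment

Genes overlap a window iff the half-open intervals intersect in ≥ 1 bp
(abutting intervals do not). BED input (0-based half-open) and GFF3
(1-based inclusive) are converted to the internal 1-based half-open
convention. Overrepresentation uses the one-sided hypergeometric upper
tail with Benjamini–Hochberg adjustment; because the stated 0.05
threshold is ambiguous between raw and adjusted p, both columns are
reported and the `significant` flag uses the adjusted value. The
universe is the set of genes overlapping any scanned window — not the
whole genome — because chip coverage biases which genes are testable
(configurable by passing a different universe).

## The simulated world

`simulate_cohort()` is a forward Wright–Fisher frequency simulator, not a
coalescent: ancestral alt frequencies are Beta(0.5, 0.5) truncated to
[0.05, 0.95] (a U-shaped, chip-ascertainment-like spectrum); lineages
drift by binomial updates $p' \sim \mathrm{Bin}(2N_e, p)/2N_e$;
individuals are Binomial(2, p) dosages; missingness is uniform at 2%.

Defaults state the world once:

* **Cohort**: the eight published breeds at their published sizes
  (total 324; indigenous 106), 20,000 SNPs on 10 chromosomes of 100 Mb —
  one SNP per ~50 kb, the density of a 50K chip on a ~2.6 Gb genome.
* **History**: a group phase (50 generations at Ne 1500) in which the
  indigenous and commercial lineages diverge — so the indigenous breeds
  form a clade, as in the real cohort — followed by 100 generations of
  independent breed drift (indigenous Ne 700–900; commercial Ne 200–450,
  encoding the stronger drift and inbreeding of intensively selected
  breeds). These Ne values put breed-level FST in the realistic
  0.1–0.2 band.
* **Selection**: 30 loci, split between the meat and milk groups, with
  the deterministic update $p' = p(1+s)/(1+sp)$, s = 0.1, applied each
  breed-phase generation before drift in the assigned group's breeds.
  The 100-generation breed phase is *not* arbitrary: the logistic sweep
  time from p = 0.05 to p > 0.99 at s = 0.1 is ≈ 100 generations, so the
  default world contains completed sweeps — the footprint the scan is
  designed for. (The first draft of this generator used 40 generations;
  its sweeps stalled at p ≈ 0.8–0.95 and the diversity scan rightly
  failed to see them. The fix was to make the world consistent with its
  own premise, not to loosen any test.)
* **Selected loci start rare-to-moderate**: drawn among loci with
  ancestral alt frequency ≤ 0.3. A "sweep" of an already-common allele
  leaves almost no FST or diversity footprint; conditioning on the
  initial frequency is standard in sweep-detection benchmarks.
* **Linkage**: loci are *unlinked* by default. LD decay, when needed, is
  produced by an explicit block-copy mode (`ld_decay_bp > 0`): within a
  block each individual's SNP genotype copies the block-anchor genotype
  with probability $1/(1+4N_e\rho d)$, a Sved-style kernel giving
  monotone decay that is stronger at small Ne.

What a green test therefore establishes — and what it does not: the
pipeline recovers completed hard sweeps of per-site effect in a drifting
multi-breed cohort with chip-like density and missingness. It does not
establish performance under hitchhiking-generated diversity troughs
(unlinked loci have none: each sweep affects exactly one SNP, so the Δπ
scan here works at single-site resolution and is tested for *enrichment*
of truth loci, which is robust, rather than high recall, which
single-site Δπ cannot deliver), nor under ascertainment schemes,
recombination-rate variation, or recent admixture, none of which are
simulated.

## Numerical and convention choices

* Coordinates are 1-based; all windows and internal gene intervals are
  half-open `[start, end)`; BED I/O converts to/from 0-based half-open.
  Windows start at 1, 1+step, ... while start ≤ chromosome extent.
* Missing genotypes are a distinct state (`NA`), never imputed; every
  statistic defines its own complete-data denominator per locus/pair.
* PED input is unpolarised; the alt allele defaults to the minor allele,
  which is cosmetic since every statistic in the package is invariant to
  allele relabelling (property-tested).
* Quantiles are nearest-rank with inclusive ties; all tie-breaks
  (pruning, NJ) are documented deterministic rules; every stochastic
  stage (simulation, LD subsampling, bootstrap) consumes an explicit
  seed, and the pipeline derives per-stage seeds from one master seed so
  reruns are byte-identical.
* Degenerate inputs: loci with no calls are flagged undefined and
  excluded from the affected statistic; monomorphic-everywhere loci have
  undefined FST; a window with no informative locus is omitted (FST) or
  reported as zero diversity (π); an empty outlier set scores recall 0
  with undefined precision.

## Known limitations

Pooled-vs-per-breed HWE and pooled-vs-s>2 FST are exposed but the
source's actual choices are unknown; the allele-sharing distance is an
assumption; the ROH caller is a maximal-run simplification; enrichment
uses a flat term map with no ontology propagation; liftOver-style build
conversion is out of scope (inputs must share one build). The simulator's
independence of loci makes LD-based statistics exercisable but not
realistic, and its two-level demography is the simplest history
consistent with the observed clade structure, not an inference.
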