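---
title: "Methods: linking a ubiquitous and a lineage-restricted transcription factor"
author: "chipcoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking a ubiquitous and a lineage-restricted transcription factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A ubiquitous transcription factor (here, YY1) can acquire
lineage-specific function by cooperating with a lineage-restricted
partner (here, the melanocyte master regulator MITF). Establishing that
claim computationally requires several independent lines of evidence,
each with its own statistical machinery:

1. genome-wide binding sites for the ubiquitous factor, from ChIP-seq
   (peak calling against a sequenced chromatin control);
2. the transcriptional consequence of depleting each factor, from
   replicate shRNA-knockdown expression profiles (robust
   differential-expression ranking);
3. evidence that the two knockdowns move the *same* genes in the *same*
   direction (co-regulation statistics);
4. evidence that the partner's DNA motif is enriched near the responsive
   genes (motif enrichment against matched random regions); and
5. interval logic connecting binding sites to genes (TSS windows,
   introns, cross-cell-type specificity, nearest-site distances).

`chipcoreg` implements each stage as tested package functions and ships
a synthetic-data module that generates inputs with the statistical
structure each stage assumes, together with the ground truth needed to
score it. The `analysis/` scripts chain the stages into the full
workflow; `run_all()` does the same in one call.

# Peak calling under a Skellam null

Reads are represented by their 5' start positions only. Windows of
`window_size` bp (default 200, a typical transcription-factor peak
scale) are placed every `step` bp (default 50). For a window with ChIP
count $c_1$ and control count $c_2$, the test statistic is the
difference $d = c_1 - c_2$. Under the null that the window contains
only background signal, $c_1 \sim \mathrm{Pois}(\mu_1)$ and
$c_2 \sim \mathrm{Pois}(\mu_2)$ independently, so $d$ follows the
Skellam distribution

$$P(D = k) = e^{-(\mu_1+\mu_2)}\left(\frac{\mu_1}{\mu_2}\right)^{k/2}
  I_{|k|}\!\left(2\sqrt{\mu_1\mu_2}\right),$$

with $I_k$ the modified Bessel function of the first kind. This plays
the same role the local Poisson null plays in MACS-style callers, but
tests the ChIP-minus-control difference directly instead of the ChIP
count alone.

The null rates come from the control track. For each window we take the
control count averaged over nested spans (1x, 5x and 25x the window,
rescaled to window units), take the maximum of those means and a
genome-wide floor — the conservative "local lambda" idea — and set
$\mu_2 = \lambda$, $\mu_1 = r\lambda$ where
$r = \text{ChIP depth}/\text{control depth}$. Scaling the ChIP
expectation up by the depth ratio (rather than down-sampling either
track) keeps both observed counts untouched; the ratio and all
parameters are recorded in the run summary. The default simulated
depths, 400k ChIP vs 250k control reads on a 2 Mb two-chromosome
genome, keep the ~15M:9M depth imbalance of a realistic
ChIP-vs-sonicated-control design at desk scale.

P-values are one-sided (enrichment only), since peak calling seeks
excess ChIP signal. Windows at $p \le 10^{-6}$ are merged when within
`merge_gap` (default one window) and peaks touching any excluded
interval (blacklist regions such as satellites and rRNA) are removed
exactly. The summit is the midpoint of the most significant window; no
finer summit model is attempted.

Numerical notes: the pmf is evaluated in log space through the
exponentially scaled Bessel function; where the order is far above the
argument (deep tails) `besselI` underflows, and the term is recovered
from the ascending power series of $I_\nu$, summed in log space. Tail
probabilities accumulate log-space terms from $d$ to 12 standard
deviations past the mode plus a fixed margin, and are floored at the
smallest positive double so a p-value is never exactly zero. Windows
are pre-screened with two rigorous lower bounds on the tail
($P(D \ge d) \ge P(X_1 \ge d)e^{-\mu_2}$ and
$P(D \ge d) \ge P(X_1 \ge d + k_0)P(X_2 \le k_0)$ with
$k_0 = \lceil\mu_2\rceil$), so the exact tail sum is only computed for
windows that could pass the cutoff; this cannot change the call set.

# RSA differential-expression ranking

Each knockdown contributes $m$ replicate experiments (default layout:
two replicates in each of three datasets for the first factor, giving
$m = 6$ columns `M1,M2,U1,U2,G1,G2`; two datasets for the second). All
$N = mG$ log fold-changes are pooled and ranked increasingly; ties are
broken deterministically by the (value, experiment, gene) triple —
documented because array data rarely ties but simulated data can.

For a gene whose sorted ranks are $r_1 < \dots < r_m$, the
down-regulation score is the minimum hypergeometric tail

$$p = \min_{j = 1..m} P(X \ge j), \qquad
  X \sim \mathrm{HG}(N, m, r_j),$$

the probability that at least $j$ of the gene's $m$ values land in the
top $r_j$ positions by chance. The minimum is reported uncorrected,
matching the redundant-siRNA-activity procedure this statistic comes
from; a Monte-Carlo-calibrated variant (`rsa_permutation_p()`) is
available but not the default. Up-regulation is scored on a second,
reversed ranking (equivalently, the negated table) rather than from the
same ranking's upper tail — both conventions are defensible; two
rankings keep the two directions exactly symmetric
(`p_up(T) = p_down(-T)` holds gene by gene, and is tested).

P-values become q-values by the Storey construction:
$\hat\pi_0 = \#\{p > \lambda\} / ((1-\lambda) n)$ capped at 1
($\lambda = 0.5$ by default; a spline-smoothed estimate over a
$\lambda$ grid is available), multiplied by the Benjamini-Hochberg
step-up values, so forcing $\pi_0 = 1$ reproduces BH exactly. The
headline gene lists use $q \le 0.01$.

# Co-regulation statistics

**Bagged lowess with a randomized-x envelope.** With $x$ the mean log
fold-change per gene after the first knockdown and $y$ after the
second, the reported trend is the pointwise mean of 100 lowess fits to
bootstrap resamples of the $(x, y)$ pairs, evaluated on a fixed
100-point grid spanning the central 98% of $x$ (the extreme 1% tails
are excluded because lowess is unstable where data are sparse). Lowess
uses span 0.3 with two robustifying iterations; the span is a
convention, exposed as a parameter. The null envelope is the pointwise
minimum and maximum of 1000 lowess fits to data whose $x$-coordinates
have been permuted, which destroys any x-y association while preserving
both marginals. The permutation can be restricted to a masked subset
(e.g. only the differentially expressed genes) — the default shuffles
all plotted genes, the more conservative reading. Exits from the
envelope are reported per grid point without multiplicity correction,
as the curve is read graphically: a trend that escapes the min/max of
1000 null curves over a contiguous region is the qualitative evidence
of co-regulation.

**Top-k overlap curves.** For each list size $k$ and each direction
mode (down/down = co-activated, up/up = co-repressed, and the two
antagonistic crosses), the top-$k$ genes of each knockdown's RSA
ranking are intersected and the overlap $v$ is scored by the one-sided
Fisher / hypergeometric tail
$P(\mathrm{HG}(U, k, k) \ge v)$ over the shared universe of $U$ genes.
Plotting the p-value across a grid of $k$ shows whether significance is
robust to the arbitrary choice of list size. The default grid
(100-500 by 100) spans the scale of the planted gene classes; at very
small $k$ the planted two-point effect distribution makes top lists
near-random subsets *within* the affected class, diluting the overlap
(see the generator discussion below), and at $k$ approaching $U$ the
statistic saturates at $p = 1$.

# Motif enrichment with an adaptive cutoff

Motifs are count matrices regularised with a background-proportional
pseudocount (1% of the column total) and scored as log2 odds against
the background composition; ambiguous bases contribute zero. Each
region's score is the best window score over both strands (region-level
presence/absence, since the downstream binomial test counts regions,
not occurrences; per-occurrence counting is a non-default option).

Rather than fixing a score threshold, every distinct observed score is
a candidate cutoff. At each cutoff the foreground hit count is tested
against the background hit rate with an exact binomial test in both
directions (the rate is clamped to
$[1/2B,\ 1 - 1/2B]$ so degenerate rates of 0 or 1 stay testable), and
the cutoff/direction minimising the p-value is reported, with both
directional p-values emitted. That minimisation is a selection over
many tests, so the minimised p-value is biased; the honest significance
is the label-permutation calibration: permute the fg/bg labels of the
pooled scores, recompute the minimised p each time, and report
$(1 + \#\{p_{perm} \le p_{obs}\})/(n_{perm}+1)$.

Matched random regions reproduce the input set's count and exact length
multiset, placed uniformly while avoiding an exclusion set. GC matching
is available as an option but off by default — "matched" is read as
count/length, the minimal assumption.

# Interval analyses

All coordinates are 0-based half-open (BED convention); the two
conversion helpers to 1-based reporting are the only place the
convention changes. Summits are annotated summits where present,
interval midpoints otherwise.

- **Overlap fraction**: an interval of set A counts once if it shares
  at least `min_overlap_bp` (default 1) with any interval of B.
  Interval intersection is the default semantics; summit-distance
  semantics are available through the specificity filter.
- **Specificity filter**: a site survives if its summit is more than
  5 kb (inclusive boundary: exactly 5 kb is "within" and removed) from
  every summit in the other conditions' site sets. This is the rule
  that isolates cell-type-specific binding sites.
- **Gene assignment**: a peak is assigned to a gene if its summit lies
  within 5 kb of the TSS, or in an intron (`mode = "intron"`, the
  default) / anywhere in the gene span (`mode = "gene_body"`). Both
  body conventions appear in practice, so both are modes; gene-body
  assignments are a strict superset of intron assignments. A peak may
  be assigned to several genes.
- **Nearest peak to TSS**: minimises |summit − TSS|, signs the distance
  in gene orientation (negative upstream), and breaks ties toward the
  smaller absolute coordinate.

# The synthetic-data module

The generators are pure functions of (spec, seed) and emit the ground
truth needed to score every stage without re-simulation.

- **ChIP tracks**: control reads uniform; ChIP reads from a
  piecewise-constant rate, `enrichment`-fold (default 8) higher inside
  `n_peaks` (50) planted, disjoint, 300-bp sites, with exactly the
  requested depths drawn. No fragment-shift model, duplicates,
  sequencing errors or mappability structure: the peak statistic
  operates on window counts, and these are the features it consumes.
- **Expression tables**: gene classes with means
  (first factor, second factor) of $(-e,-e)$ co-activated, $(+e,+e)$
  co-repressed, $(-e,+e)$ antagonistic, $(-e,0)/(0,-e)$ single-factor,
  $(0,0)$ null; replicate values add independent Normal(0, 0.3) noise
  on the log scale. Defaults: 2000 genes, 150 + 150 co-regulated,
  100 + 100 single-factor, no antagonistic genes — mirroring the
  qualitative structure the co-regulation analysis is meant to detect
  (shared targets in both directions, factor-private targets, and no
  systematic antagonism); the antagonistic class is exercised in tests.
  The two-point effect distribution (every affected gene at the same
  mean) is deliberately simple; its known artefact is that *within* a
  class the ranking is pure noise, so very small top-k lists behave
  like random subsets of the class and the overlap statistic only
  gains power once k is on the scale of the class size. Real data,
  with continuous effect sizes correlated between knockdowns, does not
  show this dilution. Passing tests therefore demonstrate the
  statistics' behaviour under the planted structure, not calibration
  on real arrays.
- **Sequences**: i.i.d. backgrounds at 41% GC (a genome-like
  composition), one motif instance planted per selected region, drawn
  column-wise from the PWM, uniform offset and strand. Defaults
  (300 + 300 regions of 300 bp, 40% vs 5% plant rates) keep the
  study-scale design of ~800 foreground and matched random regions at
  desk scale while leaving the enrichment test non-trivial.
- **Peak sets**: set B placed first; a prescribed rounded fraction of A
  (default 30%, the cross-factor overlap scale of interest) is placed
  to intersect distinct B intervals by construction, the rest disjoint
  from B, so the realised overlap fraction is exact.
- **Gene models**: disjoint multi-exon genes with uniform exon/intron
  sizes and random strands, enough structure to exercise every branch
  of the assignment rules.

# Problem sizes and reproducibility

The default benchmark uses a 2 Mb genome, 650k total reads, 2000 genes
x 10 replicate columns, 600 sequence regions, 100 + 100 peak-set
intervals and 20 gene models; the co-regulation stage fits
100 bootstrap and 1000 permutation lowess curves. These sizes give
every statistic enough data to show its planted signal crisply while a
full run completes in well under a minute on one core. Every stochastic
step takes an explicit seed; `run_all()` derives per-stage sub-seeds
from one master seed (`derive_stage_seeds()`), writes md5 digests of
every artefact into its manifest, and reproduces those digests exactly
under the same seed.

# Known limitations

- The ChIP normalisation contract (depth-ratio scaling plus
  max-of-spans local background) is a reconstruction of standard
  practice, parameterised and recorded per run, not a fitted model.
- The uncorrected minimum in the RSA statistic and in the
  adaptive-cutoff binomial p are intentionally faithful to their
  sources; both have calibrated companions that should be preferred
  when the p-value itself (rather than the induced ranking) matters.
- The synthetic generators model none of: probe-level array effects,
  RMA normalisation, mappability, duplicate reads, fragment-length
  structure, GC-dependent coverage, or correlated effect sizes. Results
  on real data additionally depend on all of these.
- Ontology-based gene-set selection and any external database retrieval
  are out of scope; motifs and gene models are user-supplied.
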