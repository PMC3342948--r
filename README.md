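# chipcoreg

Statistical toolkit for asking whether a ubiquitously expressed
transcription factor gains lineage-specific function by co-regulating
genes with a lineage-restricted partner — the analysis pattern behind
pairing a factor like YY1 with a master regulator like MITF in
melanocytes. The package implements the five computational stages such a
study needs, each testable against planted ground truth from a built-in
synthetic-data module:

1. **ChIP-seq peak calling under a Skellam null.** For a window with
   ChIP count `c1` and control count `c2`, the statistic is `d = c1 −
   c2`, whose null is the Skellam distribution
   `P(D = k) = exp(−(μ1+μ2)) (μ1/μ2)^(k/2) I_|k|(2√(μ1μ2))` with
   `μ2 = λ_local` from a max-of-nested-spans control background and
   `μ1 = r·λ_local` scaled by the ChIP/control depth ratio `r`.
   One-sided p-values at a `1e-6` cutoff, window merging, blacklist
   filtering.
2. **RSA differential-expression ranking.** All replicate log
   fold-changes are pooled and ranked; each gene is scored by
   `min_j P(X ≥ j)`, `X ~ Hypergeometric(N, m, r_j)` over its sorted
   ranks `r_1 < … < r_m` (down and up directions from two opposite
   rankings), then converted to Storey q-values
   (`q = π̂0 · BH`, `π̂0 = #{p>λ}/((1−λ)n)` capped at 1).
3. **Co-regulation statistics.** A bagged lowess curve (mean of 100
   bootstrap fits) of one knockdown's mean log fold-changes against the
   other's, with a pointwise min/max envelope from 1000 randomized-x
   lowess fits; and Fisher's exact overlap of top-k RSA gene lists in
   four direction modes across a grid of k.
4. **Motif enrichment with an adaptive cutoff.** Region-level best
   log-odds PWM scores on both strands; every distinct score is a
   candidate cutoff and the exact binomial p (over- and
   under-representation vs matched random regions) is minimised over
   cutoffs, then honestly calibrated by label permutation.
5. **Interval analyses.** Overlap fractions between peak sets,
   cell-line-specificity filtering (summits > 5 kb from every other-set
   summit), TSS-window/intron gene assignment, and signed
   nearest-peak-to-TSS distances.

All coordinates are 0-based half-open (BED). Everything stochastic is
seeded and bit-reproducible.

## Worked example

One call runs the whole benchmark — simulate, call peaks, rank both
knockdowns, build the co-regulation curves, run motif enrichment and the
interval analyses — and prints a one-page report:

```r
library(chipcoreg)
m <- run_all(seed = 42, outdir = "results/run")
report(m)
```

```
chipcoreg run (seed 42)

-- peak calling (Skellam null) --
  peaks called: 50   depth ratio r = 1.600
  vs truth: recall 1.000, false positives 0
-- RSA differential expression --
  N = 12000 pooled values, m = 6; pi0(down, MITF-side) = 0.339
  significant at q <= 0.01: 252 down / 156 up (MITF), 250 down (YY1)
  vs truth: precision 0.992, recall 1.000
-- co-regulation --
  bagged curve outside the null envelope at 71 grid points (38 in the co-activated quadrant)
  overlap curve: co-activated max p 2.18e-13, co-repressed max p 2.71e-32, antagonistic min p 1.00e+00
-- motif enrichment --
  Ebox_CATGTG: over-represented, cutoff 11.057, fg 91/300 vs bg 39/300, binomial p 3.62e-15, calibrated p 4.98e-03
-- interval analyses --
  peak-set overlap fraction: 0.300 (30 / 100)
  specificity filter retained 42 sites; 1 peak-gene assignments
  nearest peak to the first gene's TSS: -5529 bp
```

Reading the numbers: all 50 planted binding sites are recovered with no
false calls at `p ≤ 1e-6`; the 250 genes planted as down-regulated on
the MITF side are recovered at q ≤ 0.01 with 2 false discoveries; the
bagged fold-change curve escapes the 1000-permutation null envelope
exactly where co-activated genes live (lower-left quadrant); the top-k
overlap is overwhelmingly significant for co-activated and co-repressed
gene lists at every k but never for the antagonistic crosses —
the signature of genuine co-regulation; the planted E-box is
over-represented in foreground regions (91/300 vs 39/300 above the
adaptive cutoff) with a permutation-calibrated p of 0.005; and the
peak-set overlap fraction reproduces its 30% construction target
exactly.

The same workflow is available as numbered stage scripts that exchange
standard files (BED, BED12, FASTA, TSV, JSON) under `results/`:

```sh
Rscript analysis/01_simulate.R      # inputs + ground truth
Rscript analysis/02_call_peaks.R    # Skellam peak calls vs truth
Rscript analysis/03_rsa.R           # RSA ranking for both knockdowns
Rscript analysis/04_coregulation.R  # bagged lowess + envelope, overlap curves
Rscript analysis/05_motif.R         # adaptive-cutoff motif enrichment
Rscript analysis/06_intervals.R     # overlaps, specificity, gene assignment
```

The master seed defaults to 42; set `CHIPCOREG_SEED` to change it.

## Layout

```
R/                  package code: simulation, Skellam caller, RSA,
                    co-regulation, motif enrichment, interval ops, driver
analysis/           numbered stage scripts over the package functions
scripts/acceptance.R  end-to-end reproduction entry point
tests/testthat/     unit, property and acceptance tests with
                    independent oracles (convolution, enumeration,
                    brute-force scans)
vignettes/          methods vignette: models, parameters, design choices
```
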