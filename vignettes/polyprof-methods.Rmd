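---
title: "polyprof: models and methods for polysome-profiling translatome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyprof: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyprof)
```

## Overview

`polyprof` implements the computational core of a two-colour
polysome-profiling ("translatome") analysis: per-probe polysome versus
subpolysome intensity ratios are background-corrected, turned into
M-values, tested for differential polysomal association between tumour
and control samples with a rank-product permutation test, and the
resulting gene lists are characterised by 5'/3'UTR regulatory features,
feature enrichment statistics and GO-term over-representation. A
separate morphology module classifies labelled mitochondrial particle
masks. Every stage can be exercised on synthetic data with planted
ground truth.

## Background correction: the normexp model

Observed foreground intensity in one channel is modelled as
$X = B + S$ with background $B \sim N(\mu, \sigma^2)$ and signal
$S \sim \mathrm{Exp}(\text{mean } \alpha)$. `fit_normexp()` estimates
the three parameters by closed-form method of moments: the normal part
contributes no skewness, so the third central moment identifies
$\alpha = (m_3/2)^{1/3}$, then $\sigma^2 = \widehat{\mathrm{Var}} -
\alpha^2$ and $\mu = \bar{x} - \alpha$. When the implied $\sigma^2$ is
non-positive (data more skewed than an exponential), the fit falls back
to $\sigma = 0.1\,\alpha$. This moment fit was chosen over a
saddle-point likelihood because it is deterministic, closed-form and
directly testable against its own moments; it is an approximation to
the likelihood-based fits used by mainstream array pipelines.

`normexp_correct()` returns the conditional mean
$E[S \mid X = x] = m + \sigma\,\phi(m/\sigma)/\Phi(m/\sigma)$ with
$m = x - \mu - \sigma^2/\alpha$, evaluated with the Mills ratio in log
space so results stay positive and accurate arbitrarily far into the
left tail.

Two practical properties matter downstream and are verified by the test
suite rather than assumed:

* **Conditioning of $\sigma$.** When $\alpha \gg \sigma$,
  $\sigma^2$ is a small difference between two large moment estimates;
  at 50,000 draws with $\sigma/\alpha = 0.075$ its relative error is
  tens of percent even though $\mu$ and $\alpha$ recover to a few
  percent. With a non-vanishing background share all three parameters
  recover accurately.
* **Low-intensity attenuation.** The conditional mean shrinks weak
  signals toward a small positive floor, so log-ratios of weakly
  expressed genes attenuate toward zero. On synthetic data with planted
  shifts of 2 log2 units, recovered group differences average roughly
  1.1-1.3 — clearly separated from null genes, but not unbiased.
  Rank-based testing is insensitive to this compression; only the
  linear fold-change filter sees it, and planted effects still clear
  the published threshold comfortably.

## M-values

`compute_m_values()` fits one normexp model per channel per array
(dye-specific background), corrects, and forms
$M = \log_2(\text{red}/\text{green})$, negated on dye-swapped arrays so
that M always means log2(polysome/subpolysome). Probes mapping to one
gene are averaged on the M scale (order-independent). An optional
per-array median centering (`center = TRUE`, off by default) is
available; no further between-array normalisation is applied. Because
each array is fitted on its own probes, desk-scale simulations (500
probes) show visible array-level offsets from fit sampling noise that
would be an order of magnitude smaller at chip scale (~35,000 probes);
with asymmetric planting (more up- than down-regulated genes) the
channel fits also differ slightly, leaving a small positive offset on
null genes. Both effects are documented behaviour of foreground-only
per-array correction, not removed by default.

## The rank-product test

For an unpaired two-class design, all tumour x control array pairs are
formed (`pairwise_fold_changes()`); column $(t, c)$ holds
$d_g = M_{g,t} - M_{g,c}$. Within each column genes are ranked
(1 = most extreme in the tested direction, average ranks on ties) and
the rank product is the geometric mean across columns. Small rank
products flag consistently extreme genes.

Significance comes from a permutation null. The p-value of gene $g$
pools permuted rank products over all genes:
$p_g = (1 + \#\{RP_{\text{null}} \le RP_g\})/(1 + n_{\text{perm}} G)$,
with the +1 smoothing avoiding exact zeros, and the percentage of false
prediction is $pfp_g = p_g \, G / \mathrm{rank}_g$. The pfp is reported
raw (not monotonized), matching the per-gene columns of the original
tool's output; a cumulative-min variant is available behind
`monotone_pfp = TRUE`. Fold change is reported linear,
$FC = 2^{\overline{d}}$, and the selection rule is $FC \ge 2$ with
$pfp < 0.2$ (strict), the thresholds used to define the UP and DOWN
lists. Every gene appears in both lists, which is what the two-arm
volcano table (`volcano_table()`) makes explicit.

### Two permutation schemes

The classical rank-product null permutes every comparison column
independently (`null_scheme = "column"`, the default; for tiny problems
`exhaustive = TRUE` enumerates it exactly). This scheme treats the k
columns as independent. In an all-pairs design they are not: two
comparisons sharing an array correlate at about 0.5, and with 24 tumour
and 6 control arrays the 144 columns carry an effective variance
inflation of roughly 15 on mean log-ranks. The column null is therefore
anticonservative here — null p-values pile up near 0 and 1 — although
the hard fold-change filter still keeps null selections near zero.

`null_scheme = "label"` instead permutes the tumour/control labels
across arrays and rebuilds the whole fold-change matrix each time,
preserving within-array dependence. On null synthetic experiments its
p-values are uniform (KS p ~ 0.5 on average), so it is the scheme to
use when calibrated p-values or pfp estimates are the goal; the column
scheme remains the faithful reproduction of the classical method and
the default. Both schemes share the observed statistics (rank products,
ranks, fold changes), so gene ordering is identical.

Sample relatedness between arrays is summarised by
`pearson_distance_matrix()` ($1 - r$) with average-linkage
agglomeration (`cluster_arrays()`), exported as Newick.

## UTR feature annotation

All scanners operate on DNA alphabet (U mapped to T on input):

* **TOP / TOP-like** (`scan_top`): a cytosine at position 1 followed by
  at least `min_run` pyrimidines; the same pattern starting at
  positions 2-5 is TOP-like. The canonical run length is not fully
  pinned down in the literature this rule descends from, so `min_run`
  defaults to 4 and is configurable.
* **uORFs** (`find_uorfs`): an ATG whose first base is in the 5'UTR,
  read in its own frame through the concatenated 5'UTR+CDS to the first
  stop codon, which must end strictly before the last base of the CDS;
  total length at least 9 nt including the stop. Overlapping uORFs all
  count, and a stop inside the CDS is allowed — the definition imposes
  no exclusions.
* **AREs** (`scan_are`): non-overlapping, leftmost-first matches of
  TATTTAT[AT][AT] in the 3'UTR.
* **TISU** (`tisu_flag`): primary mode is membership in a curated gene
  list; an optional consensus mode matches SAASATGGCGGC (S = G/C)
  across the start codon with at most one mismatch outside the
  invariant ATG.
* **5'UTR structure** (`utr5_mfe`): the default builtin backend
  maximises nested base pairs (Watson-Crick, optionally G-U wobble,
  minimum hairpin loop 3) by dynamic programming in C++ and reports
  minus the pair count. This is a structure *proxy*: monotone within a
  run but not on the kcal/mol scale. Because base-pair maximisation
  saturates near half the sequence length on random sequences, it
  separates composition-driven structure classes only weakly; when the
  `RNAfold` executable is available, `backend = "external"` reports
  true minimum free energies instead. Sequences under 5 nt score 0.

## Enrichment statistics

Binary features use Pearson's chi-squared without continuity correction
(a flag enables Yates) on the 2x2 table of list versus the rest of the
chip; continuous features (5'UTR length, folding score) use the
two-sided Welch t-test. GO-term over-representation uses Fisher's exact
test per term against a configurable reference list (default: the whole
universe), reporting the sample odds ratio $(ad)/(bc)$ rather than the
conditional MLE, and raw p-values by default with Benjamini-Hochberg
behind a flag — matching the way such tables are conventionally
printed.

## Morphology

`shape_descriptors()` measures labelled particle masks: area as pixel
count times pixel area; major/minor axes from the eigenvalues of the
second central moments (moment-equivalent ellipse, axis length
$4\sqrt{\lambda}$); perimeter by Moore-neighbour contour tracing with
$\sqrt2$-weighted diagonal steps; circularity $4\pi A/P^2$ clamped at 1.
Chain-code tracing overestimates smooth perimeters by 3-5%, so
rasterized circles measure circularity ~0.92-0.95 — comfortably above
the 0.8 classification bound for near-circular particles. Particles
touching the grid border are excluded by default (truncated shapes bias
every descriptor); labels under 5 pixels are skipped with a warning.

`classify_particles()` applies strict thresholds: elongated when
major/minor > 3; otherwise enlarged when circularity > 0.8 and area >
0.5 um^2; otherwise other. Elongation takes precedence so classes are
disjoint counts. `field_summary()` compares per-field elongated and
enlarged counts between two conditions with a two-sided Mann-Whitney
test — exact by full enumeration of group assignments up to 8 fields
per condition (two-sided by symmetric deviation of U from its null
mean, so identical count vectors give p = 1), and a tie-corrected
normal approximation beyond that.

## The synthetic-data generator

The generator defines the study conditions the package is tested under:
8 tumour and 2 control samples with 3 repeats each (30 arrays), one
repeat per sample dye-swapped; 500 genes by default with 10% planted up
and 5% down at a 2 log2-unit shift and per-gene, per-array M noise of
0.5 (0.3 in null-calibration runs).

Intensities follow the model the correction assumes: truncated-normal
background (mean 80, sd 12) plus an exponential signal (mean 2000)
scaled by $2^{\pm M/2}$ in the two channels, with a per-gene log-normal
baseline (sdlog 0.3) providing dynamic range. The background scale and
the mild baseline heterogeneity were fixed once, on the grounds that
the generator should keep the normexp model approximately
well-specified on its output: heavier baseline tails
(e.g. sdlog 1) make the signal marginal so far from exponential that
the moment fit degrades and fold changes compress below the detection
threshold — a regime that would test the fit's misspecification rather
than the pipeline.

Transcripts are built to carry exactly their planted features: motifs
are inserted (and accidental matches removed) and the result is
verified with the package's own scanners, retrying with fresh random
backbones until all planted flags are confirmed; an infeasible request
(e.g. a 5'UTR too short for its uORFs) raises an error naming the gene.
Up-regulated genes default to shorter 5'UTRs (log-normal around 70 nt
versus 150 nt), fewer uORFs, more TISU elements and less structure than
background — the qualitative profile the feature-enrichment stage is
expected to detect. A synthetic GO map annotates genes at 5% per term,
with three terms enriched 3-fold in the planted up set. Particle fields
rasterize non-overlapping ellipses whose parameters are drawn to
satisfy their class with margin (elongated ratio 3.5-6; enlarged
near-circular with area 0.7-1.4 um^2; other below 0.4 um^2), with
rejection-sampled placement capped at 10,000 attempts.

What the generator does *not* emulate: spatial/print-tip artefacts,
within-array trends, probe-level quality differences, real GO topology,
image noise beyond rasterization. Passing tests therefore demonstrate
the statistical machinery under its stated model, not robustness to
every artefact of real arrays.

## Numerical and design choices

* All randomness flows from explicit integer seeds; component
  substreams use fixed offsets, so pipelines are byte-reproducible
  (`run_pipeline()` writes no timestamps into outputs).
* Rank-product tie handling: average ranks; list positions break RP
  ties by first occurrence.
* Permutation p-values use +1 smoothing; exhaustive enumeration (small
  G, k) reports exact unsmoothed tail probabilities; comparisons use a
  1e-9 tie tolerance in log space.
* The canonical tabular format is TSV (tab separator, header, `.`
  decimal, no quoting) so outputs diff bit-exactly.
* Problem sizes in tests (500 genes, 1000 permutations, 10-20
  simulation seeds, fields of ~12 particles) are the package's
  desk-scale defaults; they mirror the study design's shape while
  keeping simulations comfortably reproducible.

## Known limitations

* The moment-based normexp fit degrades when channel signal is a
  mixture over a wide dynamic range (alpha inflates, see above); a
  likelihood fit would be more robust and could be added behind the
  same interface.
* Raw (non-monotonized) pfp can be non-monotone along the ranked list.
* The builtin folding proxy is not an energy model; treat it as a
  within-run ordering only.
* The morphology module measures provided label masks; it does not
  segment micrographs.
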