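# polyprof

Differential **polysomal-association analysis** for two-colour
polysome-profiling microarrays, in R.

Polysome profiling separates mRNAs that are actively translated (bound
by polysomes) from those that are not (subpolysomal fractions). When the
two pools are hybridised to a two-colour array, the per-probe value
`M = log2(polysome / subpolysome)` is a proxy for translation
efficiency, and comparing M between tumour-derived and control samples
identifies mRNAs whose *translation* — not transcription — is
selectively rewired. `polyprof` implements the full analysis chain for
this design, plus the downstream sequence and morphology analyses that
typically accompany it:

* **normexp background correction** — intensities are modelled as
  normal background plus exponential signal, `X = B + S`,
  `B ~ N(mu, sigma^2)`, `S ~ Exp(mean alpha)`; parameters are fitted by
  closed-form moments and each observation is replaced by
  `E[S | X = x] = m + sigma * phi(m/sigma) / Phi(m/sigma)` with
  `m = x - mu - sigma^2/alpha`.
* **rank-product differential translation** — per-gene fold changes
  over all tumour x control array pairs are ranked per comparison and
  combined as `RP_g = (prod_i r_gi)^(1/k)`; permutation p-values and the
  percentage of false prediction `pfp_g = p_g * G / rank_g` support the
  selection rule *fold change >= 2 at pfp < 0.2*, producing UP and DOWN
  lists (each gene is scored in both directions, as in a two-arm
  volcano plot). Two permutation nulls are provided: the classical
  per-column scheme and a calibrated array-label scheme for all-pairs
  designs.
* **5'/3'UTR feature annotation** — TOP/TOP-like motifs (C + pyrimidine
  run at positions 1 / 2-5), upstream ORFs (ATG in the 5'UTR, in-frame
  stop before the CDS end, >= 9 nt), AU-rich elements
  (`TATTTAT[AT][AT]`), TISU elements, 5'UTR length, and a base-pair
  maximisation folding proxy (or real `RNAfold` energies when
  available).
* **enrichment statistics** — chi-squared tests for binary features and
  Welch t-tests for continuous ones against the rest of the chip;
  Fisher's exact test with sample odds ratios for GO-term
  over-representation.
* **mitochondrial particle morphology** — moment-based shape
  descriptors of labelled masks and the classification *elongated*
  (axis ratio > 3) / *enlarged* (circularity > 0.8 and area > 0.5 um^2),
  with exact Mann-Whitney comparisons of per-field counts.
* **synthetic data with planted truth** — a generator for arrays,
  transcripts, GO maps and particle fields that makes every stage
  testable end to end.

## Worked example

```r
library(polyprof)

design <- sim_design(n_genes = 500, seed = 1)   # 8 tumour vs 2 control, x3 repeats
sim <- gen_array_experiment(design)             # two-colour arrays with dye swaps
mv  <- compute_m_values(sim$experiment)         # normexp-corrected M values
#> mvalue_table: 500 genes x 30 arrays

rp  <- rank_product_test(pairwise_fold_changes(mv), n_perm = 1000, seed = 1)
head(rp[order(rp$rank_up), c("gene", "FC", "rank_up", "pval_up", "pfp_up")], 5)
#>     gene       FC rank_up      pval_up       pfp_up
#> 19 g0019 3.317691       1 1.999996e-06 0.0009999980
#> 40 g0040 3.130165       2 1.999996e-06 0.0004999990
#> 27 g0027 2.974218       3 1.999996e-06 0.0003333327
#> 30 g0030 3.001552       4 1.999996e-06 0.0002499995
#> 47 g0047 2.921799       5 1.999996e-06 0.0001999996

sig <- significant_genes(rp)                    # FC >= 2 and pfp < 0.2
length(sig$up); length(sig$down)
#> [1] 41
#> [1] 23
```

The top-ranked genes carry fold changes around 3 (the planted 4-fold
shift, attenuated by background correction of weak intensities) at pfp
well below the 0.2 cut; 41 of the 50 planted up-regulated genes are
recovered. Annotating the matching synthetic transcripts and testing
the UP list against the rest of the chip reproduces the expected
regulatory profile:

```r
tr <- gen_transcripts(design)
ft <- annotate_transcripts(tr$records, tr$tisu_list)
feature_enrichment_panel(sig$up, ft)
#>    feature  test statistic        p odds_ratio direction
#> 1      top chisq     0.840 3.59e-01      1.664  enriched
#> 2     uorf chisq    24.983 5.78e-07      0.138  depleted
#> 3      are chisq     0.228 6.33e-01      0.745  depleted
#> 4     tisu chisq    41.619 1.11e-10     26.057  enriched
#> 5 utr5_len     t   -18.062 2.25e-32         NA     lower
#> 6 utr5_mfe     t    17.671 1.97e-31         NA    higher
```

Translationally up-regulated transcripts have shorter, less structured
5'UTRs with fewer uORFs and a strong TISU enrichment, while TOP and
ARE rates do not differ — exactly the planted structure. A single call
runs the whole chain and writes every table (M values, rank-product
results, gene lists, volcano, clustering, features, enrichments):

```r
run_pipeline("results_dir", pipeline_config(design = design, n_perm = 1000))
```

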