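# tepair

Homotypic transposable-element (TE) pairing at focal chromatin contacts.

Chromatin-conformation assays (Micro-C, Hi-C) record pairs of genomic loci
that touch in the nucleus. This package asks whether the two anchors of a
contact share TE content of the *same* family more often than chance —
homotypic coupling — by contrasting two kinds of loci on a 600 bp binned
contact map at 8–40 kb separations:

* **hotspots**: single 600 × 600 bp bin pairs whose count stands out focally
  from a low local background. Within the 5 × 5 grid centred on a candidate
  (4 corners excluded, 21 cells kept), the centre must have ≥ 5 contacts,
  reach ≥ 1.2× the second-highest retained cell, and exceed 2.5× the
  background median (median < 0.4 × centre).
* **coldfields**: extended contact-depleted regions matched one-to-one to
  hotspots by minimising `TMC = max(grid)^1.3 × median(grid)` over diagonal
  offsets `0, ±5, …, ±95` bins (±57 kb), preserving anchor separation.

Around each anchor, TEs with centres within ±11 kb are assigned to 21
sliding windows of 2 kb at 50% overlap (centre window −1…+1 kb). A family
present in window *w* at both anchors scores one homotypic pairing; two
different families score a heterotypic pairing. Per family, three metrics
follow:

```
hot/cold ratio      = homotypic counts at hotspots / at coldfields
heterotypic ratio   = heterotypic counts at hotspots / at coldfields
specificity index   = hot/cold ratio / heterotypic ratio
```

plus the pairwise hot/cold specificity matrix, head–head/head–tail strand
orientation, family-age correlation, cross-dataset Pearson correlation and
average-linkage clustering, and an off-lattice (580 bp) misbinning negative
control. A synthetic-data generator plants known hotspots and known TE
coupling so the whole chain is testable against ground truth.

Intended users: computational (epi)genomics researchers analysing `.pairs`
contact data against repeat annotations, or studying the method itself.

## Worked example

```r
library(tepair)

demo <- run_demo(seed = 1, out_dir = "tepair_demo")
demo$metrics[, .(family, hot_homotypic, cold_homotypic,
                 hot_cold_ratio, specificity_index)]
```

The demo simulates a 600 kb genome with 40 planted focal hotspots, each
carrying a guaranteed same-family ERVL pair within ±1 kb of both anchors
(`coupling_prob = 1`), over a Poisson contact background and an hg38-like
TE catalog. It then runs the full pipeline and prints:

```
   family hot_homotypic cold_homotypic hot_cold_ratio specificity_index
1:   AluY           104            108      0.9629630         0.9608696
2:   ERVL            74             42      1.7619048         1.5666667
3:   L1M5            37             25      1.4800000         1.3668235
4:    L2a            33             32      1.0312500         1.0209718
5:   MIRb            41             54      0.7592593         0.8459015
6:  SVA_D             1              0             NA                NA
```

The planted family (ERVL) shows a clearly elevated homotypic hot/cold ratio
and tops the specificity-matrix diagonal; uncoupled families scatter around
1 (SVA is too rare at this genome size to define a ratio — it is flagged
`NA`, never imputed). The run summary (`tepair_demo/summary.txt`) reports
the negative control:

```
hot/cold pairs called: 413
coupled-family central hot/cold ratio (600 bp): 1.762
coupled-family central hot/cold ratio (580 bp control): 1.104
head-head / head-tail: 1.005
```

Reconstructing anchor coordinates with deliberately wrong 580 bp bins
drifts every anchor by 20 bp per bin index — effectively reshuffling
coordinates against the TE annotation — and collapses the planted ratio
toward 1, confirming the signal is not a pipeline artifact. The strand
orientation ratio sits at 1, as it must for a strand-symmetric generator.

The stages behind `run_demo()` are all exported, e.g.:

```r
rec  <- stream_pairs("contacts.pairs.gz", sampling_plan(1e6, 8e5, 2.5e6))
rec  <- rec[filter_band(rec)]
map  <- bin_contacts(rec, 600)
calls <- call_all(map)                       # hotspots + matched coldfields
tab  <- pairing_counts(calls, read_te_bed("te.bed"))
family_metrics(tab)
specificity_matrix(tab, top_k = 30)
```

## Package layout

| Path | Contents |
|---|---|
| `R/synthetic.R` | genome/TE/contact generator with planted truth |
| `R/contacts.R` | `.pairs` streaming, sampling plan, band filter, binning |
| `R/spotcaller.R` | 5×5-grid hotspot criteria, TMC coldfield search |
| `R/te_catalog.R` | BED-like TE input, 10 kb bucket index, flank queries |
| `R/pairing.R` | sliding windows, pairing counts, family metrics |
| `R/repro.R` | correlation, clustering, misbinning control |
| `R/pipeline.R` | configuration, end-to-end pipeline, demo |
| `vignettes/tepair-methods.Rmd` | model, parameters, design decisions |
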