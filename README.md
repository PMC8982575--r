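# mirab

An in-silico companion to the miR-AB shRNAmir system. miR-AB is a
miR-E-derived pri-microRNA backbone whose lower stem is replaced by BamHI
and ApaI restriction sites, so that a gene-specific shRNAmir can be cloned
from two annealed synthetic oligos instead of PCR or Gibson assembly. This
package implements the computational side of that workflow for people who
design, clone and read out shRNAmir experiments:

* **Oligo design** — convert a 97-nt shRNAmir sequence (as produced by
  SplashRNA- or shERWOOD-style predictors) into the two cloning oligos.
  The fixed layout is

  ```
  top    (75 nt) = GATCC + G + sense(22) + loop(19) + guide(22) + T + GGGCC
  bottom (67 nt) = revcomp(top[5..71])
  ```

  so the annealed duplex carries a 5′ `GATC` (BamHI-compatible) overhang on
  one end and a 3′ `GGCC` (ApaI-compatible) overhang on the other. The
  published table of cloning oligos is bundled and every pair is
  regenerated character-for-character by the implementation.
* **Cloning simulation** — restriction digestion with typed sticky ends,
  exact-complement annealing, ligation of compatible ends into circular
  constructs, restriction-site screening and a seeded mock vector with a
  stuffer between the cloning sites.
* **Colony verification** — simulated Sanger reads from constructs and a
  loop-anchored verifier that classifies colonies positive/negative
  against an expected cassette in either orientation.
* **Codon recoding** — removal of forbidden restriction sites from
  protein-coding sequences (the toolkit's fluorescent reporters and the
  puromycin marker) by deterministic synonymous codon substitution.
* **Panel planning** — the bundled reporter → (laser, band-pass filter)
  channel map for the eight fluorescent reporters, and a bipartite-matching
  feasibility check that a label set is pairwise distinguishable on a given
  instrument.
* **Barcode demultiplexing** — a seeded generator of per-cell flow
  cytometry events for cotransduced reporter barcodes, quantile gating
  against an untransduced control, assignment of every event to one of the
  2^n barcode populations, and per-population MFI / knockdown
  quantification (`knockdown% = 100 × (1 − MFI_pop / MFI_control)`).

## Worked example

```r
library(mirab)

# design oligos for a 97-nt shRNAmir
tab  <- mirab_oligos()                       # bundled published pairs
cass <- parse_oligos(tab$top[11], tab$bottom[11], name = tab$name[11])
pair <- design_oligos(cass)
pair
#> <oligo_pair> CD4_sh1_Human
#>   top:    GATCCGACCTGATCATCAAGAATCTTAATAGTGAAGCCACAGATGTATTAAGATTCTTGATGATCAGGGTGGGCC
#>   bottom: CACCCTGATCATCAAGAATCTTAATACATCTGTGGCTTCACTATTAAGATTCTTGATGATCAGGTCG

# clone it into the seeded mock vector and verify a simulated colony read
vec       <- make_mock_vector(seed = 1)
construct <- clone_oligos(vec, pair)
read      <- simulate_read(construct, primer_offset = 2300, read_len = 700,
                           sub_rate = 0, seed = 1)
verify_read(read, cass)
#> <verify_report> POSITIVE (forward)

# can six reporters share a four-laser sorter?
feasible_assignment(c("Azurite", "GFP", "Ametrine", "mOrange",
                      "mCherry2", "E2-Crimson"), instrument("4laser"))
#> <channel_assignment> feasible
#> # A tibble: 6 x 2
#>   label      channel
#>   <chr>      <chr>
#> 1 Azurite    405nm:450/40
#> 2 GFP        488nm:530/30
#> 3 Ametrine   405nm:510/50
#> 4 mOrange    488nm:582/15
#> 5 mCherry2   561nm:610/20
#> 6 E2-Crimson 633nm:660/20

# simulate a four-reporter barcode experiment and quantify knockdown
cfg   <- sim_config(n_cells = 50000, seed = 1)
ctrl  <- simulate_events(sim_config(
           n_cells = 50000,
           reporters = dplyr::mutate(default_reporters(), p = 0), seed = 2))
gated <- gate_events(simulate_events(cfg), ctrl,
                     reporters = default_reporters()$name)
kd    <- quantify_knockdown(gated, c(CD127 = "none"))
dplyr::filter(kd, population == "Azurite+")
#> # A tibble: 1 x 7
#>   population stain n_events   mfi control_mfi knockdown_percent flagged
#>   <fct>      <chr>    <int> <dbl>       <dbl>             <dbl> <lgl>
#> 1 Azurite+   CD127     5152  99.9       1003.              90.0 FALSE
```

The knockdown column reads directly as "shCD127-carrying cells retain ~10%
of control CD127 staining". `autoplot(kd)` draws the per-population
knockdown panel; `plot_events(gated)` shows the gated intensity
distributions.

A command-line entry point wrapping the same functions ships at
`system.file("cli", "mirab.R", package = "mirab")` with subcommands
`design`, `parse-oligos`, `clone`, `digest`, `screen`, `verify`, `recode`,
`panel` and `demux`.

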