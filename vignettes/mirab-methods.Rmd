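---
title: "Models and design choices behind the mirab toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the mirab toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirab)
```

This vignette records the scientific model behind each part of the
package, the parameters that matter, and the choices made where the design
was genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The miR-AB oligo layout

A gene-specific shRNAmir differs from any other only in its upper stem
(the 22-nt sense and guide strands) and keeps the 19-nt loop and the
backbone flanks. Replacing the lower stem with BamHI and ApaI sites means
the only sequence that must be synthesized is

```
top    (75 nt) = GATCC + G + sense(22) + loop(19) + guide(22) + T + GGGCC
bottom (67 nt) = revcomp(top[5..71])
```

whose annealed duplex presents a 5′ `GATC` overhang (the BamHI half-site)
and a 3′ `GGCC` overhang (the ApaI half-site). These constants are **not**
assumed: they were derived by parsing every bundled published oligo pair
and confirming a single consensus — the test suite re-derives prefix,
suffix, loop and the bottom-strand relation from the fixture before any
other oligo test runs. The bundled table has 30 pairs; all layout
properties are asserted over every row.

Within the 97-mer the regions are (1-based): 5′ flank 1–18, sense 19–40,
loop 41–59, guide 60–81, 3′ flank 82–97. All internal coordinates in the
code are 0-based half-open; the user-facing documentation uses 1-based
closed intervals because that is how biologists read sequence positions.

`parse_oligos()` fills the flanks of a parsed cassette with the canonical
constants, because the oligos do not encode them: `reconstruct_97()` is
canonical-flank reconstruction, not recovery of a user's original flanks.

Validation has two modes. The original conversion tool documents exactly
one check — the 97-nt length gate — and `lenient` mode mirrors that.
`strict` mode (the default) also requires the canonical loop at 41–59 and
warns on internal BamHI/ApaI sites in the stem region, which would be cut
during cloning; it is stricter than the original tool on purpose, in the
same error-proofing spirit.

## Cloning simulation

A restriction enzyme is modeled by its recognition site and the offsets of
the two strand cuts within it; the overhang and its polarity follow from
the offsets (BamHI `G^GATCC` → 5′ `GATC`; ApaI `GGGCC^C` → 3′ `GGCC`). The
registry carries the enzymes used by the vector system; the BamHI/ApaI
definitions are validated in-repo against the oligo-pair arithmetic (the
designed top oligos begin `GATCC` and end with the unpaired `GGCC` tail).

A fragment is stored by its forward-strand *extent* — every position
occupied by either strand — with each end typed by polarity and overhang
length. Under this representation two compatible ends join exactly when
the left fragment's extent tail equals the right fragment's extent head,
and the junction is restored by concatenating past the shared overhang.
This makes the two key invariants mechanical: a correctly assembled
construct reads `GGATCC` and `GGGCCC` at the two junctions, and
digest → ligate → digest round-trips recover the insert exactly.

Two deliberate simplifications:

* **Orientation.** `ligate()` joins fragments only in the orientation they
  are supplied. The two distinct sticky ends make the protocol
  directional, and the intended product uses each fragment once; inverted
  head-to-head concatemers (which palindromic overhangs would permit
  chemically) are out of scope, as are partial digests, star activity and
  methylation sensitivity.
* **Circular identity** is equality up to rotation, canonicalized as the
  lexicographically minimal rotation, so construct comparison is
  deterministic. Reverse-complement identity is not folded in; the
  simulator always reports circles in the forward orientation of their
  constituent fragments.

The true vector sequences are distributed as plasmids and are not printed
anywhere re-usable, so all construct-level work uses `make_mock_vector()`:
a seeded random circular plasmid with exactly one BamHI and one ApaI site
flanking a random stuffer (default 800 bp, matching the ~800 bp stuffer of
the real vectors) on a backbone rejection-sampled to be free of both
sites. It is labelled synthetic throughout; its stuffer content is
arbitrary by construction and nothing downstream depends on it.

## Colony verification

Simulated Sanger reads are exact (wrapped) substrings of the construct
with independent uniform substitutions at a configurable rate;
substitution-only is a fair model of the high-quality central stretch of a
Sanger read, and indels/chromatogram artefacts are deliberately not
modeled. The verifier anchors on the 19-nt loop because the loop is
construct-invariant: an exact 19-mer match is overwhelmingly unlikely by
chance in a few-kb plasmid, and alignment-free anchoring beats full
alignment at this scale. Both orientations are searched; the 22-mers
flanking the anchor are then compared against the expected sense and guide
with a mismatch budget (default 0 — the strictest reading of what a
"positive" sequencing result means, since the criterion is not spelled out
in the source protocol). Reads that do not cover the whole
sense–loop–guide window are negative with a coverage note, never an error.

## Codon recoding

Site removal is specified as a goal, not an algorithm, so the package
fixes a deterministic greedy rule: scan for forbidden motifs on both
strands; for the leftmost hit try the overlapping codons left to right
and, within a codon, synonymous codons in lexicographic order; accept the
first substitution that destroys the hit without creating a new forbidden
hit within ±6 codons; re-scan to a fixpoint so junction-created hits are
caught. Determinism and verifiability were preferred over minimizing the
number of substitutions globally; the greedy rule is minimal per hit.
Codon-usage optimization (the usual second goal of commercial "codon
optimization") is intentionally out of scope — only site removal is
specified. A hit overlapping only Met/Trp (and stop codons, which are
never rewritten) is reported as unresolvable rather than silently left in
place.

## Panel planning

Distinguishability is modeled as *channel exclusivity*: two labels
conflict if and only if they are forced onto the same (laser, band-pass
filter) detection channel. This is exactly the granularity of the bundled
channel table and of the practical guidance it encodes (Azurite and
mTagBFP2 need the UV laser to separate; GFP and Venus share 488/530;
mOrange is indistinguishable from PE). Quantitative spectral overlap and
compensation are out of scope on purpose — the guidance this reproduces is
channel-based, and the demultiplexing module assumes a panel that already
passed this check.

Feasibility is a maximum bipartite matching between labels and instrument
channels restricted to each label's usable channels (igraph's matching
under the hood; an independent exhaustive-search oracle in the tests
confirms agreement on every reporter subset of size ≤ 6). When a panel is
infeasible the report includes a smallest Hall-violator subset — the
minimal set of labels that jointly have fewer usable channels than
members — which is the actionable piece of information ("drop one of
these").

Two instrument presets ship: `4laser` (405/488/561/633 nm) and `5laser`
(adds 355 nm). The source material describes the same sorter both ways in
different places; both presets are provided rather than resolving the
discrepancy, and every published feasibility call checked in the tests
holds on the preset it was made on.

## Barcode demultiplexing

`simulate_events()` is the package's synthetic stand-in for a cotransduced
multicolor experiment, and its defaults are the study conditions, chosen
once: four reporters (Azurite, GFP, Ametrine, mCherry2), transduction
probability 0.3 each (independent infection; this keeps the untransduced
fraction below 50% and the smallest, quadruple-positive population near
0.8% — the regime the readout was demonstrated in), log10 intensities
2.0 ± 0.15 (negative) and 3.5 ± 0.20 (positive) — a typical two-decade
separation on a cytometer — stain control MFI 1000 with 0.1 log10
multiplicative measurement noise, and knockdown 0.9 per target, linked
one-to-one to reporters. What the generator does *not* emulate: spectral
spillover (panel feasibility is a precondition), autofluorescence
structure, doublets, and any correlation between co-infecting viruses.
Passing tests therefore show estimator correctness under the stated noise
model, not robustness to compensation artefacts in real data.

Gating mimics the manual procedure reproducibly: each reporter's threshold
is the 99.9th percentile of an untransduced control sample, and each event
is assigned to one of the 2^n populations named `none`, `Azurite+`, …,
`Azurite+GFP+Ametrine+mCherry2+` (ordered by number of positive reporters,
then reporter order). MFI defaults to the geometric mean because the
intensities are log-normal — the geometric mean is unbiased for the
location parameter and agrees with how cytometry software displays log
data; the arithmetic mean is available since the original analysis
software's statistic is not documented. Knockdown is
`100 × (1 − MFI_pop / MFI_control)` against a per-stain control population
(usually `none`). Populations under 100 events are flagged, never dropped,
so small barcodes stay visible with an honesty marker.

Problem sizes used by the checks: the estimator-recovery property runs 10
seeds at 200,000 cells with knockdowns 0.5/0.7/0.9 and requires mean
absolute error ≤ 0.02; routine tests use 20,000–150,000 cells, which is
the scale at which population MFIs stabilize to a point or two of percent.

## Numerical and degenerate-input conventions

* `U` in input sequences is converted to `T` with a warning (RNA paste-in
  is the most common user error); any other non-ACGT character is an error
  naming the position.
* Motif search is exact; circular sequences are searched across the
  origin and hits reported at forward-strand offsets in `[0, n)`.
* A digest with zero sites returns the input uncut with a message, not an
  error; a ligation with no compatible ends returns an empty product list
  with a message.
* All stochastic functions take explicit seeds and are bit-reproducible;
  no function depends on the global RNG state it does not set.

## Known limitations

* The mock vector is a stand-in: absolute construct coordinates differ
  from the real plasmids, so only relative/insert-level conclusions carry
  over.
* The verifier's exact loop anchor fails on reads whose errors fall inside
  the loop; `anchor_tolerance` exists for that case but defaults to 0.
* The recoder's greedy rule can in principle use more substitutions than a
  global optimum, and refuses (by design) to touch stop codons.
* FCS files are not read or written; event tables are plain CSV.
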