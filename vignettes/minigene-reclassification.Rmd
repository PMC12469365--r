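---
title: "Minigene splice assays: quantification and reclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minigene splice assays: quantification and reclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minisplice)
```

## The assay and its decision variable

A minigene splice assay clones a genomic region of interest — a run of
exons with their introns — between two reporter exons, transfects the
construct into cells, and reads the spliced products out by RT-PCR with
primers in the reporter flanks. Each product's size is the two flank
lengths plus whatever exonic (or aberrantly included intronic) sequence
survived splicing, so gel electrophoresis separates the species and
densitometry of the lane estimates their relative abundance.

The clinically decisive quantity is the **residual wild-type fraction**:
the percentage of correctly spliced product. The gene-specific ClinGen
rule set implemented here maps it to ACMG evidence:

| residual wild-type | bin    | criterion          | final class |
|--------------------|--------|--------------------|-------------|
| exactly 0%         | `none` | PVS1 (very strong) | P           |
| 0% < x < 5%        | `sub5` | PVS1 (strong)      | LP          |
| 5% ≤ x < 20%       | `low`  | none               | unchanged   |
| x ≥ 20%            | `high` | none               | unchanged   |

Two side rules: a fully splice-silent assay (100% wild-type) for a
synonymous or non-canonical splice-site variant earns BP7 at strong
strength and a benign call, because splicing was the only mechanism by
which such a variant could act; a splice-silent *missense* variant keeps
its prior class, since a protein-level mechanism remains open. PP3
(supporting, in-silico) is recorded for reporting whenever the highest
SpliceAI delta score reaches 0.2, but never changes a class by itself.

The bin boundaries are half-open ([5, 20) and [20, 100]) because that is
the partition under which the packaged 59-assay cohort reproduces its
published 7/11/41 split exactly; the `sub5` bin is empty in that cohort.
An enzyme-activity route to PS3-supporting exists in the underlying
guidelines but is explicitly discouraged for splice assays and is not
implemented.

## Coordinates, events, consequences

All positions are HGVS coding (c.) coordinates: 1-based, closed
intervals, with signed intronic offsets (`643+5` is 5 nt into the intron
after position 643; `1129-293` is 293 nt before position 1129). Interval
lengths are `end - start + 1`. Codon index is `floor((base-1)/3) + 1`.

Observed aberrant products are described by a small event algebra — exon
skips, pseudo-exons, exon truncations/elongations, intron retentions —
which serializes deterministically to r. strings (`r.644_725del`,
`r.1338_1339ins1339-2_1339-1`). A tolerant parser reads the same dialect
back, including the run-on compound style (`644_725del_999_1128del`) used
in assay tables; `parse_identity()` additionally converts prose
descriptions ("Exon 7 skipping (92%)") into structured species.

Protein consequences are computed from sequence: the altered CDS is
rebuilt (intronic insertions are looked up in the model's intron
sequences), both sequences are translated, and the first differing
residue anchors the notation. Frameshifts are named
`p.<Ref><pos><New>fs*N` with N counted from the first changed residue to
the new stop inclusive; a missing downstream stop reports `fs*?`.
In-frame changes become `del`/`delins` names via longest-common-suffix
alignment. `first_affected_codon()` is the coordinate-only lower bound on
the p. position; it can sit one codon before the true first *changed*
residue when the junction codon resynthesizes the reference amino acid
(the exon-12 skip in the packaged data is the worked example: coordinate
bound 415, sequence-level first change 416).

## The packaged study data and the synthetic sequence stand-in

The package ships, as plain-text fixtures, a published *RPE65* minigene
cohort: 73 prioritized variants (SpliceAI ≥ 0.1 within a 5000-bp window,
prior class at most VUS) and 59 quantified assays across four wild-type
constructs (WT-1: exons 1–5, WT-2: 3–6, WT-3: 6–10, WT-4: 11–13; reporter
flanks fixed at 150/130 nt, a plausible choice — the true primer
geometry is not published and no test depends on it). Exon boundaries for
exons 4–13 follow exactly from published r. intervals; the exon 1–3
splits and the final exon are inferred and flagged, and nothing asserts
them.

The CDS and intron sequences are **synthetic stand-ins**, constructed
under constraints rather than downloaded: every reference residue implied
by published p. notations, every reference nucleotide implied by c.
tokens, and the published frameshift outcomes of the main single-event
products are satisfied simultaneously, and were verified against
brute-force surgery-plus-translation before the fixture was frozen. The
stand-in supports exact reproduction of calls like `p.Asp215Valfs*4`, but
it is *not* the RefSeq sequence: analyses of real patient data must load
a real transcript model via `read_transcript_model()`.

Two arithmetic quirks of the source tables are preserved rather than
repaired: one row's printed fractions total 103% (flagged by the
`consistent` column, never an error), and one product is described as a
5-bp truncation while its r. interval spans 6 nt (the fixture keeps both;
only the r. arithmetic is asserted).

## Densitometry: numerical choices

The lane pipeline is deliberately simple and fully inspectable:

* **Background**: a 1-D morphological opening (rolling minimum then
  rolling maximum, window 201 samples) estimated on a lightly smoothed
  copy (running mean, 15 samples) and subtracted. The window must exceed
  the widest *cluster* of adjacent bands, not just one band — an opening
  narrower than a cluster climbs into the inter-band valleys and eats
  area. The profile is extended by linear extrapolation before the
  opening because a truncated opening under-reaches a ramp by
  slope × window/2 at the edges.
* **Detection**: local maxima of a 9-sample running mean, kept when their
  topographic prominence exceeds both 5% of the profile maximum and six
  times the profile MAD (noise-adaptive), and when the peak rises clearly
  above the noise floor (median + 2 MAD). The practical detection limit
  is therefore a few percent of the tallest band.
* **Integration**: trapezoids over the band support — outward from each
  peak until the signal meets the noise floor, clipped at valleys shared
  with neighbours — above a flat pedestal at the profile median.
  Fractions are areas over the lane total × 100. Band area is taken
  proportional to molar fraction directly; no size correction is applied,
  matching how assay tables report percentages.
* **Calibration**: ordinary least squares of log10(size) on migration
  position over the ladder rungs (≥ 3, strictly size-decreasing), R²
  reported. Identity assignment is greedy by decreasing band area to the
  nearest predicted fragment size within 30 bp.

Artefact species (heteroduplex-like bands flagged in the source tables)
stay inside the 100% denominator by default, matching the published
percentages; `baseline_adjust()` optionally flags species that match a
construct's constitutive baseline (e.g. partial exon-7 skipping at 39% in
WT-3) within a tolerance, and is OFF by default for the same reason.

## What the generators emulate — and what they do not

`sim_model()` draws exon/intron lengths from stated ranges (re-drawing
until at least one exon can shift the frame), builds a stop-free CDS, and
derives constructs as sliding exon windows. `sim_variant_table()` places
variants exonic/NCSS/deep-intronic and draws four-component SpliceAI-like
score vectors: a configurable fraction is engineered to pass the default
filter (Beta-distributed scores rescaled to [0.1, 1], mass concentrated
between 0.1 and 0.3 with a high tail — stylized after the published
score spread, not fitted), with predicted sites inside or outside the
5000-bp window at a stated rate. `sim_lane()` renders Gaussian bands
(σ = 6 px) at the migration positions implied by predicted fragment sizes
and an internal 100–2000 bp ladder (8 rungs, linear in log-size), over a
constant-plus-drift background with white noise.

The **SNR convention** required a decision the source material leaves
open: `snr` is defined as the peak-to-noise ratio of the *weakest* band,
so "lanes with SNR ≥ 20" qualifies every band of the lane. Under the
alternative (tallest-band) convention, the ±2-point recovery guarantee is
unattainable for any estimator: white noise at sd = max-peak/20 puts
≈1% standard error on a band's fraction (Cramér–Rao), so some of a few
hundred band measurements must exceed 2 points. The per-band reading
makes the stated guarantee meaningful and is, we think, what a gel that
"looks clean enough to quantify every band" actually has.

`sim_cohort()` draws residual wild-type fractions from the empirical
shape of the packaged cohort (a point mass at 0, a 6–19% band, a ≥ 20%
majority including fully silent assays), splits the aberrant remainder
over one or two skip products whose fragments stay ≥ 4σ apart, and
renders duplicate lanes per assay, mirroring duplicate transfections.

Not emulated: gel smearing, heteroduplex artefacts, lane-to-lane
bleed-through, saturation, and sequencing chromatograms. A green
synthetic test therefore establishes that the *pipeline arithmetic* is
right under the stated noise model — not that any real gel will be as
kind.

## Degenerate inputs and edge behaviour

Malformed c. tokens error by name; an explicit `+0` offset is rejected.
Lanes need ≥ 32 samples, strictly increasing positions, finite
non-negative intensities. A profile with no detectable band yields an
empty band table, not an error. Ladders with < 3 rungs or non-monotone
sizes error. An assay listing aberrant species while claiming 100%
wild-type errors at classification. Fractions are reported unrounded;
the published tables round to whole percent, and tests compare at that
precision.

## Limitations

* The final-class mapping is the gene-specific one (PVS1-very-strong
  alone → P), not a full ACMG evidence combiner; population-frequency
  criteria are out of scope.
* `first_affected_codon()` is a coordinate bound, not the HGVS first
  changed residue; use `protein_consequence()` when sequence is loaded.
* The greedy nearest-size identity assignment cannot distinguish
  co-migrating products (e.g. a pseudo-exon insertion that matches a
  skip's size); real studies resolve these by sequencing, which has no
  computational counterpart here.
* The packaged sequences are synthetic stand-ins (see above).
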