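# minisplice

Minigene splice-assay quantification and ACMG splice-evidence
reclassification.

## The problem

Variants of uncertain significance (VUS) in *RPE65* decide whether a
patient with Leber congenital amaurosis or retinitis pigmentosa is eligible
for gene-augmentation therapy. For variants predicted by SpliceAI to
disturb splicing, an in vitro minigene assay can supply the missing
functional evidence: the variant region is cloned between reporter exons,
expressed in cells, and the spliced RT-PCR products are separated on a gel.
The decision variable is the **residual wild-type transcript fraction**
measured by densitometry. Under the gene-specific ClinGen rules, complete
absence of wild-type transcript supports PVS1 at very-strong strength
(class P); under 5% residual supports PVS1-strong (LP); a splice-silent
result for a synonymous or non-canonical splice-site (NCSS) variant, where
splicing is the only plausible mechanism, supports BP7 at strong strength
(class B).

`minisplice` implements the computational side of that pipeline, end to
end and offline:

* **Transcript model** — HGVS c. coordinates with intronic offsets, exon
  maps, codon arithmetic (`codon_index(644)` = 215), variant-site
  classification (exonic / canonical ±1,2 / NCSS / deep-intronic) and
  minigene construct geometry with fragment-size prediction.
* **Variant intake** — LOVD/ClinVar-style tables, deduplication, and the
  selection filter: prior ACMG class at most VUS, any of the four SpliceAI
  delta scores (acceptor/donor gain/loss) at or above 0.1 with the
  predicted site within 5000 bp.
* **Densitometry** — gel-lane profiles: morphological-opening background
  subtraction, prominence-based band detection, valley-bounded trapezoidal
  integration, semi-log ladder calibration (migration vs log10 size), and
  nearest-size identity assignment against predicted fragments.
* **Splice consequences** — an event algebra (exon skip, pseudo-exon,
  truncation, elongation, intron retention) serialized to HGVS r. strings
  (`r.644_725del`), length/frame arithmetic, and sequence-based protein
  calls (`p.Asp215Valfs*4`, with fs\*N counted to the new stop inclusive).
* **Reclassifier** — residual-fraction binning (0 / <5 / 5–20 / ≥20%),
  criteria assignment, cohort summaries.
* **Synthetic data** — seeded generators for transcript models with CDS,
  variant tables with SpliceAI-like score vectors, and Gaussian-band gel
  lanes with ground truth, so every stage is testable without downloads.

The package ships the published *RPE65* study data as plain-text fixtures:
the 73 prioritized variants, the 59 quantified assays, and the transcript
model. The CDS/intron sequences are a clearly labelled *synthetic
stand-in* (`rpe65_sequences_synthetic.json`) consistent with every
published reference residue, nucleotide and frameshift consequence, but
not the RefSeq sequence.

## Worked example

```r
library(minisplice)
model    <- rpe65_model()
assays   <- rpe65_assays(model)     # 59 quantified minigene assays
variants <- rpe65_variants()        # 73 prioritized candidates

cls <- assign_criteria(assays, variants, model)
dplyr::filter(tidy(cls), final_class == "P")
#>   c_notation variant_type construct wt_pct bin   site_class criteria final_class
#> 1 c.643+5G>A NCSS         WT-3           0 none  NCSS       PVS1_ve… P
#> 2 c.644-5T>A NCSS         WT-3           0 none  NCSS       PVS1_ve… P
#> 3 c.650A>T   Missense     WT-3           0 none  exonic     PVS1_ve… P
#> 4 c.999-3C>G NCSS         WT-3           0 none  NCSS       PVS1_ve… P
#> 5 c.1334A>G  Missense     WT-4           0 none  exonic     PVS1_ve… P
#> 6 c.1338+3A… NCSS         WT-4           0 none  NCSS       PVS1_ve… P
#> 7 c.1339-3C… NCSS         WT-4           0 none  NCSS       PVS1_ve… P

glance(cls)[, c("n", "bin_none", "bin_low", "bin_high", "n_no_effect",
                "class_P", "class_B")]
#>       n bin_none bin_low bin_high n_no_effect class_P class_B
#> 1    59        7      11       41          15       7       9
```

Seven assays show no residual wild-type transcript and reclassify to
pathogenic; eleven fall in the 5–20% band and forty-one at or above 20%,
fifteen of which are fully splice-silent.

Protein-level consequence of the recurrent exon-7 skip:

```r
protein_consequence(exon_skip(7), model)
#>   r_notation   delta_len frame      p_notation      first_affected_codon
#> 1 r.644_725del       -82 frameshift p.Asp215Valfs*4                  215
```

Quantifying a simulated gel lane built from the constitutive 61/39
wild-type / exon-7-skip mixture of the WT-3 construct:

```r
cfg  <- sim_config(seed = 1)
mix  <- tibble::tibble(events = list(splice_events(), exon_skip(7)),
                       fraction = c(61, 39))
lane <- sim_lane(cfg, model$constructs[["WT-3"]], mix, model)
quantify_lane(lane$profile, lane$ladder, model$constructs[["WT-3"]], model) |>
  dplyr::select(center, size_bp, fraction, identity)
#>   center size_bp fraction identity
#> 1    360    913.     60.7 WT
#> 2    392    830.     39.3 skip_7
```

`autoplot()` methods are provided for lane profiles (with band shading)
and for classified cohorts (residual-bin bar chart by final class).

## Acceptance script

`scripts/acceptance.R` recomputes the study-anchored target quantities
from the installed package — the first affected codon of the exon-7 skip
via coordinate-only codon arithmetic, and the inserted length of the
c.1339-3C>G acceptor-shift product parsed from the packaged assay table —
and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/minigene-reclassification.Rmd` documents the model and rule
set, the tunable parameters, what the synthetic generators do and do not
emulate, and the numerical choices inside the densitometry pipeline.
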