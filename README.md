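# organellar

Spatial proteomics of bulk tissue by serial centrifugation: `organellar`
turns a protein-by-sample label-free quantification (LFQ) table over
subcellular fractions into per-subject organelle profiles, marker-trained
organelle assignments with cross-subject confidence tiers, and an
entropy-based screen for disease-associated protein re-localization.

It is written for analysts working with differential-centrifugation
fractionation experiments — for example frozen post-mortem brain tissue
separated into seven fractions (nuclear pellet through cytosolic
supernatant) from a case/control cohort — who want a tested, reproducible
path from a MaxQuant-style `proteinGroups.txt` to a ranked list of
candidate re-localized proteins.

## The model

For subject *s*, protein *p* and fraction *f* with quantification
LFQ(s, p, f), the unit of analysis is the **proportional fraction
profile**

```
ratio(s, p, f) = LFQ(s, p, f) / Σ_f LFQ(s, p, f)
```

a 7-part composition that strips between-sample abundance scale and keeps
only how the protein partitions across the gradient. On top of it:

* **Organelle assignment.** A radial-kernel SVM per subject, trained on
  organelle marker proteins randomly down-sampled to 35 per class
  (balanced classes), 10-fold cross-validated over a 10×10 grid of the
  kernel width σ and cost C. Non-marker proteins are classified
  subject-by-subject; tiers summarize control-subject agreement
  (HIGH ≥ 4/5 agree, LOW all-distinct or no dominant class, MEDIUM
  otherwise).
* **Re-localization statistic.** The normalized Shannon entropy
  `H = −Σ ratio · log2(ratio) / log2(n)` of each (protein, subject)
  profile (1 = spread evenly over the n fractions, 0 = confined to one),
  with missing intensities set to 1e-10 beforehand; the **global delta
  entropy** is mean control entropy minus mean case entropy, and proteins
  are ranked by its magnitude.
* **Per-fraction confirmation.** Two-sample Student t-tests of the ratios
  in each (protein, fraction), Benjamini–Hochberg adjusted over the whole
  protein × fraction family; candidates are proteins significant in at
  least one fraction at adjusted p < 0.05.

A synthetic-data module generates complete datasets with known ground
truth (organelle archetype profiles, Dirichlet compositional noise,
lognormal abundance, intensity-dependent dropout, planted re-localization
effects), so every stage is testable without raw mass-spectrometry data.

## Worked example

```r
library(organellar)

ds <- simulate_dataset(sim_config(n_nonmarkers = 500, n_effect = 10, seed = 42))

profiles <- to_proportions(ds$lfq, ds$design)                       # zero policy
entropy  <- entropy_table(to_proportions(ds$lfq, ds$design,
                                         missing_policy("epsilon")))
tests    <- within_fraction_tests(profiles)
head(rank_candidates(entropy, tests), 3)
#> # A tibble: 3 x 8
#>    rank protein_id delta_entropy mean_entropy_control mean_entropy_case
#>   <int> <chr>              <dbl>                <dbl>             <dbl>
#> 1     1 NP00412           -0.284                0.639             0.923
#> 2     2 MK0313            -0.140                0.505             0.645
#> 3     3 MK0043            -0.134                0.676             0.809
#>   significant_fractions n_significant any_significant
#> 1 "1,5,6"                           3 TRUE
#> 2 ""                                0 FALSE
#> 3 ""                                0 FALSE
```

The top-ranked protein is the one whose fraction profile is most
re-ordered between groups: `NP00412` has delta entropy −0.284, i.e. its
signal is spread across the gradient noticeably more evenly (on the
normalized 0–1 entropy scale) in cases than in controls, and its
`significant_fractions` column says the within-fraction tests confirm the
shift in fractions 1, 5 and 6. The next two rows are marker proteins with
sizeable delta entropy but no significant fraction — ranking and testing
deliberately disagree there, which is why candidates require both. On
this seed, 8 of the 10 planted effects are recovered among the
`any_significant` candidates.

Classification works the same way from the simulated marker catalog:

```r
cls  <- classify_all_subjects(ds$lfq, ds$design, ds$markers, seed = 42)
cons <- consensus_confidence(cls, ds$design)
table(cons$tier)
#> HIGH MEDIUM    LOW
#>  483     41      8
```

The full pipeline — filters, cohort summary, PCA, ANOVA/Tukey, marker
profiles, SVM + consensus, entropy, tests, ranking, TSV outputs and a run
manifest — is one call:

```r
dir <- tempfile(); write_fixture(ds, dir)
cfg <- pipeline_config(
  lfq_path      = file.path(dir, "proteinGroups.tsv"),
  metadata_path = file.path(dir, "metadata.tsv"),
  markers_path  = file.path(dir, "markers.tsv"),
  out_dir       = file.path(dir, "run"), seed = 42)
run_pipeline(cfg)
```

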