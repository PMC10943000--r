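# hdpheno

Rule-based phenotyping of hypertensive disorders of pregnancy (HDP) from
longitudinal cohort records.

Large birth-cohort studies transcribe prenatal care — an intake interview,
repeated checkups with blood pressure (BP) and urine-protein dipstick (PU)
readings, a delivery record, and short free-text clinical notes — for tens
of thousands of pregnancies. Labelling every pregnancy by clinician chart
review does not scale; `hdpheno` provides two deterministic, configurable
rule engines that do it programmatically:

* **Algorithm 1** (American/ACOG concepts) classifies on hypertensive
  disease history, BP ≥ 140/90 mmHg, dipstick proteinuria (single 2+ or
  1+ twice), timing of onset relative to 20 weeks (140 days), and
  PE-related clinical conditions (platelets < 100×10³/µL, creatinine
  > 1.1 mg/dL, transaminases > 2×ULN, dated notes of new-onset headache,
  visual disturbance, pulmonary edema).
* **Algorithm 2** (Japanese/JSOG concepts) additionally upgrades
  hypertensive subjects without proteinuria — GH→PE and CH→SPE — on
  maternal organ-dysfunction flags mined from notes (epigastralgia, HELLP
  syndrome, eclampsia, FGR, renal/hepatic dysfunction) or a
  light-for-date infant (< 10th percentile birth weight for week and sex).

Each subject gets exactly one of `GH_EO, GH_LO, SPE_EO, SPE_LO, PE_EO,
PE_LO, CH, NT` (early/late onset split at 34 weeks = 238 days), an onset
day, and an evidence trail. Proteinuria completing before 20 weeks is
attributed to pre-existing renal disease and suppresses the PU criterion,
avoiding overestimation of HDP.

The package also ships dictionary-driven note mining with negation
handling (English + Japanese seed terms), the study-inclusion filter
(delivery record, BP **and** PU data, live birth, not withdrawn),
validation against reference-standard diagnoses (PPV / NPV / accuracy /
sensitivity / specificity with not-applicable handling), a synthetic
pregnancy-cohort generator with ground truth, and a small CLI.

## Worked example

```r
library(hdpheno)

cfg <- sim_config(n_subjects = 500, seed = 42, noise_free = TRUE)
sim <- simulate_cohort(cfg)                   # bundles + ground truth
bundles <- mine_cohort(sim$bundles)           # fill note-derived flags
r1 <- classify_cohort(bundles, algorithm = 1)
r2 <- classify_cohort(bundles, algorithm = 2)

mean(r1$label == sim$truth$label)
#> [1] 1
mean(r2$label == sim$truth$label)
#> [1] 0.996

compare_algorithms(r1, r2)$discordant
#>   subject_id label1 label2                             rule
#> 1     S00269  GH_LO  PE_LO  light_for_date;upgrade_GH_to_PE
#> 2     S00364     CH SPE_LO light_for_date;upgrade_CH_to_SPE
```

Algorithm 1 recovers the generative truth exactly on this noise-free
cohort; algorithm 2 relabels two subjects whose infants happened to be
light-for-date — precisely the upgrade path that distinguishes the JSOG
concepts, and the only kind of discordance the construction permits
(GH→PE and CH→SPE edges).

`format_percentage()` implements the exact half-up count-to-percentage
arithmetic used in the reporting tables:

```r
format_percentage(1813, 22452)
#> [1] 8.08
```

File-based runs go through `run_phenotype()` / `run_validate()` /
`run_simulate()` or the `inst/cli/hdpheno` script
(`hdpheno phenotype --cohort dir/ --out out/ --algorithm both`), which
write label CSVs, a subtype count summary, an evidence JSON, a
discordance table and a run manifest.

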