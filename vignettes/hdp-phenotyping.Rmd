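---
title: "Rule-based phenotyping of hypertensive disorders of pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based phenotyping of hypertensive disorders of pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpheno)
```

## The phenotyping problem

Hypertensive disorders of pregnancy (HDP) — gestational hypertension (GH),
preeclampsia (PE) and superimposed preeclampsia (SPE) — affect roughly 2–8%
of pregnancies and differ substantially in pathogenesis and risk, as do
their early-onset (EO) and late-onset (LO) forms. Large birth-cohort
studies transcribe prenatal-care records (an intake interview, repeated
checkups with blood pressure and a urine-protein dipstick, a delivery
record, and short free-text clinical notes) for tens of thousands of
pregnancies, far beyond what clinician chart review can label. `hdpheno`
implements two deterministic rule engines over such records:

* **Algorithm 1** follows American (ACOG) clinical concepts: hypertensive
  disease history, blood pressure (BP), proteinuria (PU), timing of onset,
  and PE-related clinical conditions (thrombocytopenia, renal or hepatic
  dysfunction on laboratory values; new-onset headache, visual disturbance
  or pulmonary edema on dated notes).
* **Algorithm 2** follows Japanese (JSOG) concepts: identical, except that
  hypertensive subjects *without* proteinuria are upgraded — GH to PE and
  chronic hypertension (CH) to SPE — when a maternal organ-dysfunction flag
  (epigastralgia, HELLP syndrome, eclampsia, FGR, renal or hepatic
  dysfunction, mined from notes) appears at or after 20 weeks, or the
  infant is light-for-date (LFD).

Every subject receives exactly one of eight labels: `GH_EO`, `GH_LO`,
`SPE_EO`, `SPE_LO`, `PE_EO`, `PE_LO`, `CH`, `NT` (normotensive), together
with the disorder onset day and an evidence trail of fired rules.

## The decision procedure

Gestational age is stored as integer days since the last menstrual period;
week $W$ maps to days $[7W, 7W+7)$, so "before 20 weeks" means `< 140`
days and the EO/LO cut at 34 weeks means onset `< 238` days.

1. **Hypertension onset** is the first visit with SBP $\ge$ 140 mmHg or
   DBP $\ge$ 90 mmHg (inclusive cuts; a single qualifying visit by
   default — cohort visit spacing rarely supports the guidelines'
   short-interval confirmation, but `bp_repeat_count` makes the predicate
   require $k$ visits).
2. **Proteinuria** becomes positive on the first day at which a single
   dipstick $\ge$ 2+ occurs, or $\ge$ 1+ has occurred at two distinct
   visits. Proteinuria in early pregnancy is commonly caused by
   pre-existing renal insufficiency or chronic kidney disease rather than
   HDP; to avoid overestimating HDP, any qualifying pattern completing
   before 140 days disables the proteinuria channel for the whole
   pregnancy. The subject remains eligible for GH, CH, or PE/SPE via
   PE-related conditions — the early-PU rule suppresses the PU criterion
   only, because the confounder it guards against (CKD) invalidates the
   dipstick evidence, not the blood-pressure evidence.
3. **Chronic-hypertension status** holds if the subject has a hypertensive
   disease history (self-reported interview OR a non-negated note mention)
   or hypertension onset before 140 days.
4. **Labels**: no hypertension and no chronic status → `NT`. Chronic
   status with new-onset proteinuria or a PE-related condition at/after
   140 days → `SPE`, otherwise `CH`. New-onset hypertension at/after 140
   days with proteinuria or a condition → `PE`, otherwise `GH`.
5. **Timing**: the disorder onset is the day the last defining criterion
   is first satisfied (for PE, `max(htn_onset, earliest qualifying
   feature)`; for SPE, the earliest superimposed feature). EO iff onset
   `< 238` days. `CH` and `NT` carry no timing suffix.

Algorithm 2 applies its upgrades *after* this decision: a GH subject
becomes PE and a CH subject becomes SPE when an organ-dysfunction flag is
present with a dated mention at/after 140 days, or the infant is LFD.
The upgraded onset is the later of the hypertension onset and the earliest
qualifying flag day. LFD is ascertained at delivery and carries no
antepartum timing, so an LFD-only upgrade keeps the base disorder's onset
day; for a CH subject whose chronic status rests on history alone (no
measured hypertension at/after 140 days) the delivery day is used — the
only day at which the upgraded diagnosis is knowable.

### Boundary conventions

BP cuts are inclusive (`>=`); platelets fire strictly `< 100` x 10^3/uL,
creatinine strictly `> 1.1` mg/dL, transaminases strictly `> 2 x` the
upper limit of normal (defaults 30 U/L each); LFD is strictly below the
10th-percentile cutoff. A missing laboratory value never fires a
condition: absence of data is never treated as evidence. All of these,
and every other numeric threshold, are fields of `hdp_thresholds()` and of
the shipped `thresholds_default.yaml`.

## Note mining

The preprocessing step mirrors rule-based pattern matching over clinical
notes: a per-category term dictionary (English and Japanese seed terms;
the engine, not the lexicon, is the contract) is matched against
NFKC-normalized, case-folded text. ASCII terms anchor at word boundaries
(so "eclampsia" never fires inside "preeclampsia"); Japanese terms match
as substrings because the script has no delimiters. A hit is negated when
a cue ("no", "denies", "なし", ...) falls within a 10-character window
before the term, or a post-positive cue ("ruled out", "なし") within the
window after it. Negation handling is deliberately conservative: the
upstream transcription process gives no guarantee that every mention is
affirmative, and an over-eager matcher would overestimate exactly the
organ-dysfunction flags that drive algorithm 2's upgrades. Undated
mentions of timing-dependent conditions are not accepted as new-onset
evidence, since their position relative to the 20-week boundary is
unverifiable; the history flag needs no timing and accepts undated
mentions.

## The light-for-date reference

`inst/extdata/lfd_reference_synthetic.csv` is a synthetic percentile table
(flagged as such in its name): median weight by completed week follows a
Gompertz growth curve reaching ~3000 g at 40 weeks, with a ±3% sex offset
and normal-theory percentiles at a 12% coefficient of variation. It makes
the LFD predicate fully testable without redistributing a published
chart; `is_light_for_date()` accepts any table with `week`, `sex` and
`pNN` columns, and a real national reference should be substituted for
production phenotyping.

## The synthetic cohort generator

`simulate_cohort()` generates pregnancies with the statistical structure
the classifiers consume, plus ground-truth labels. Default conditions:

* **Prevalences** follow the subtype mix reported when these rule engines
  were applied to a 22,452-subject Japanese birth cohort: GH 3.96%,
  SPE 1.35%, PE 2.61%, CH 2.41%, normotensive the remainder; EO fractions
  356/890 (GH), 207/304 (SPE), 140/587 (PE).
* **Visit schedule** is the standard Japanese prenatal cadence: every
  4 weeks to week 23, every 2 weeks to week 35, weekly to delivery.
* **BP** is drawn around a subject baseline (110/68 mmHg, subject sd 8/5,
  visit sd 4) with a post-onset elevation (+45/+30, sd 6/4). No
  autocorrelation is modelled: independent draws around a state-dependent
  mean are sufficient to exercise threshold predicates, which is what the
  classifiers consume.
* **Onset days are drawn on the visit schedule**, because in observational
  data onset is only ever observed at a checkup; this makes the generative
  onset day recoverable exactly.
* **PE/SPE features**: 80% of PE/SPE show dipstick proteinuria from
  onset, 20% instead show an elevated creatinine (the condition route),
  which is what makes creatinine missingness consequential.
* **LFD** is an explicit per-class probability (default 30% in PE/SPE,
  2% elsewhere) and birth weight is then drawn *consistently with that
  status* from the percentile reference. LFD here models placental
  dysfunction, concentrated in the PE spectrum; the unconditional 10% of
  infants below the 10th percentile includes constitutionally small
  infants that the generator deliberately does not emulate, because a
  10% background rate would make algorithm 2 relabel a visible share of
  generative-GH subjects by construction.
* **Notes** are short template sentences carrying dictionary terms, with
  negated decoys ("no headache, denies visual disturbance") injected at a
  10% rate under noise.

With `noise_free = TRUE` all sds are zero and emissions deterministic, so
classifier output equals generative truth up to two documented structural
leaks: the small baseline LFD rate in GH/CH subjects (algorithm 2
upgrades them, by design of the JSOG concepts) — about 0.13% of subjects
in expectation — and nothing else. The recovery experiments in the test
suite and acceptance script run at n = 2000, which keeps the whole suite
under a minute while leaving binomial noise well below the 1% recovery
margin.

What passing these tests does *not* show about real data: the generator
has no transcription errors, no intrapartum/postpartum information (the
classifiers never see any — a documented limitation of antepartum-only
cohort data, not something the rules patch), no BP autocorrelation, no
covariate structure (age, BMI), and notes far simpler than clinical prose.

## Validation

`evaluate_all()` compares phenotyped labels with reference-standard
(chart-review) diagnoses in a binary manner per target — the HDP
aggregate, GH/SPE/PE pooled and split by timing, CH, NT — and reports
PPV, NPV, accuracy, sensitivity and specificity. A metric whose
denominator is zero is *not applicable* (`NA`), exactly as a performance
table shows a dash when no subject carries a label. Display rounding is
half-up at two decimals; the same exact-integer half-up rule drives
`format_percentage()`, which reproduces count percentages such as
1813/22452 → 8.08 (the quotient is 8.075004…).

## Degenerate inputs and tie-breaks

Duplicate visit rows at one gestational age collapse; conflicting values
merge toward detection (higher BP and dipstick grade, more abnormal lab),
with the conflict logged — a conservative choice matching the screening
intent. An empty cohort after filtering yields a zero-count summary and a
warning, not an error. Malformed rows are reported alongside the ingest
result rather than silently dropped; structural schema problems stop with
the offending column or row named.

## Worked example

```{r example}
cfg <- sim_config(n_subjects = 500, seed = 42, noise_free = TRUE)
sim <- simulate_cohort(cfg)
bundles <- mine_cohort(sim$bundles)
r1 <- classify_cohort(bundles, algorithm = 1)
r2 <- classify_cohort(bundles, algorithm = 2)
summarize_labels(r1)
compare_algorithms(r1, r2)$discordant
mean(r1$label == sim$truth$label)
```

## Known limitations

* Postpartum-onset disease is out of reach: the input is antepartum
  checkup data, and subjects who first present intrapartum or postpartum
  will be under-called relative to a chart review that sees those data.
* Severity grading, and eclampsia/HELLP as *output* labels, are out of
  scope (they enter only as input flags).
* The dictionary is a seed lexicon; production use on Japanese notes
  should extend it per site, and no morphological analysis is attempted.
* Whether the early-PU rule should remove subjects from HDP entirely
  rather than only suppressing the PU criterion is a genuine ambiguity in
  the clinical concepts; the channel-suppression reading implemented here
  is the narrower intervention and is flagged at the rule site.
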