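# psarag

Decision support for guideline-concordant prostate-specific antigen (PSA)
testing, plus the complete harness needed to evaluate such a tool.

Whether to offer a man a PSA test — and at what interval — depends on two
long society guidelines (European Association of Urology, EAU; American
Urological Association, AUA) that sometimes disagree, on an estimate of
the patient's remaining life expectancy, and on special situations where
the PSA value misleads (active urinary tract infection, heavy comorbidity)
or does not suffice (abnormal digital rectal examination). Junior and
generalist clinicians get this wrong often enough that automated,
auditable support is attractive. `psarag` is aimed at clinical
informaticians building or evaluating such support.

## What the package implements

* **Charlson Comorbidity Index gate** — age-adjusted CCI from a controlled
  19-condition vocabulary with the classical 1/2/3/6 weights (editable
  YAML), ten-year survival `S₁₀ = 0.983^exp(0.9·CCI)`, and two hard gates:
  age > 72 years, or `S₁₀ < 0.5` ("not expected to live at least 10
  years"), both configurable and bypassable.
* **Dual-guideline rule engine** — deterministic, config-driven EAU and
  AUA recommendation rules (elevation thresholds, confirmatory repeat for
  moderately elevated PSA up to 10 ng/mL, referral on confirmed or >10
  ng/mL elevation, 2-year EAU follow-up, 2–4-year AUA screening for ages
  50–69, UTI and DRE overrides), with per-guideline answers reconciled:
  concordant pairs merge (interval intersection), discordant pairs are
  both presented.
* **Retrieval-augmented pipeline** — corpus chunking with content-hash
  ids, per-guideline BM25 retrieval (k1 = 1.2, b = 0.75), prompt assembly
  (expert persona, chain of thought, constrain-to-context, example output
  structure), and a pluggable text-in/text-out generation backend: a
  deterministic mock (delegates to the rule engine) and a scripted replay
  backend (for failure-mode injection) ship with the package; no network
  is ever required.
* **Evaluation harness** — binomial grading against gold labels
  (concordance with *either* guideline counts as correct) with a four-way
  error taxonomy (unnecessary: short interval / did not require; missed:
  long interval / failed to offer), per-category and pooled accuracy
  reports, Fleiss κ with item-bootstrap confidence intervals, and t /
  two-proportion accuracy comparisons. A reconstruction of the published
  three-arm rating table ships as a fixture.
* **Synthetic cohort generator** — seeded, gold-labelled 44-case cohorts
  over the five study categories (11/9/9/8/7; 20 screening / 24
  follow-up cases).

## Worked example

```r
library(psarag)

case <- parse_case(list(case_id = "demo", age = 67,
  comorbidities = list("diabetes_uncomplicated", "myocardial_infarction"),
  psa_history = list(list(value = 2.4, months_ago = 0))))

cci <- cci_score(case)
cci
#> CCI score 4 (comorbidity 2 + age 2); 10-year survival 0.534

screening_gate(case, cci)
#> gate: eligible

run_pipeline(case, pipeline_config())$dual
#> Concordant recommendation:
#> [EAU+AUA] routine_interval [24-24 mo] +shared-decision  (eau.routine_followup_interval, aua.routine_followup_interval)
```

Diabetes and a prior myocardial infarction contribute 1 point each; age
67 adds 2, so the CCI is 4 and estimated ten-year survival 0.534 — above
the 0.50 gate, so the case proceeds. His latest PSA (2.4 ng/mL) is below
the 3.0 ng/mL elevation threshold and he is inside the 50–69 band, so both
guidelines agree on routine follow-up; the merged interval is the
intersection of the EAU 2-year and AUA 2–4-year intervals, flagged for
shared decision-making, and every fired rule is cited.

Evaluating the shipped reconstruction of the published rating table:

```r
rep <- aggregate_ratings(load_table1_fixture())
rep[rep$category == "overall",
    c("arm", "n", "unnecessary_subtotal", "missed_subtotal", "total_errors", "accuracy_pct")]
#>           arm   n unnecessary_subtotal missed_subtotal total_errors accuracy_pct
#>           llm 220                    5               5           10     95.45455
#>  human_closed 220                   43              40           83     62.27273
#>    human_open 220                   33              24           57     74.09091

fleiss_kappa(rating_matrix(load_table1_fixture(), arm = "llm"))
#> [1] 1
```

The tool arm is correct in 95.5% of ratings versus 62.3% (closed-book) and
74.1% (open-book) for the clinician arms, and its ratings are unanimous
across runs (κ = 1).

## Command line

```sh
exec/psarag simulate --seed 7 --out cases/
exec/psarag batch --cases cases/ --backend mock --out results/
exec/psarag evaluate --results results/ --gold cases/gold_labels.csv --report report.csv
exec/psarag evaluate --fixture table1 --report table1_report.csv
exec/psarag build-index --corpus inst/extdata/corpus --out index.jsonl
```

Every artifact-producing run writes a `.manifest.json` (subcommand,
options, seed, versions) sufficient to re-run it identically with the
deterministic backends.

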