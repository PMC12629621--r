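---
title: "Guideline-concordant PSA testing: model, pipeline and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guideline-concordant PSA testing: model, pipeline and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psarag)
```

## The clinical problem

Prostate-specific antigen (PSA) testing is the standard tool for early
detection of prostate cancer, but deciding *whether* and *when* to test a
given man requires juggling two long guideline documents (from the European
Association of Urology, EAU, and the American Urological Association, AUA),
an estimate of the patient's remaining life expectancy, and special
situations in which a PSA value is misleading (active urinary tract
infection, significant comorbidity) or insufficient (abnormal digital
rectal examination, DRE). `psarag` implements a decision-support pipeline
for exactly this task, together with the full harness needed to evaluate
such a pipeline: a four-way error taxonomy, accuracy comparisons, Fleiss
kappa interrater agreement, and a seeded synthetic case generator.

## Pipeline model

The pipeline mirrors how a careful clinician would proceed:

1. **Comorbidity and life expectancy.** The age-adjusted Charlson
   Comorbidity Index (CCI) is computed from a controlled vocabulary of the
   19 Charlson conditions (weights 1/2/3/6, shipped as an editable YAML
   table; when a mild and a severe form of the same organ system are both
   coded, only the severe weight counts) plus one point per decade of age
   from 50. Ten-year survival is the classical transform
   $S_{10} = 0.983^{\exp(0.9\,\mathrm{CCI})}$, so a score of 0 maps to
   0.983 and survival decreases strictly with the score.
2. **Gating.** Men older than 72 years, or with estimated ten-year
   survival below 0.50, are not passed on to screening recommendation:
   screening cannot benefit men unlikely to live another decade. Both the
   age limit and the survival threshold are configuration, and the gate
   can be disabled outright at the clinician's discretion
   (`gate_config(enabled = FALSE)`). "Expected to live at least 10 years"
   is operationalised as $S_{10} \ge 0.5$ — the natural reading of
   "expected" — because no explicit probability cutoff is standard; the
   threshold is a config value precisely so users can disagree. The age
   gate is evaluated first and both refusal reasons are reported when both
   fail, giving a reproducible audit trail.
3. **Per-guideline recommendation.** Separate answers are generated from
   the EAU rules and the AUA rules, then reconciled. Concordant answers
   (same action, overlapping intervals) merge into one recommendation with
   the intersection of the intervals — intersection because it is
   conservative and order-independent; discordant answers are both
   presented, labelled by source, since when the societies disagree a
   decision aid should show both positions rather than silently pick one.

### The codified rule subset

The engine is a deterministic, config-driven encoding
(`inst/extdata/guideline_rules.yaml`) of the PSA early-detection rules,
with explicit rule identifiers so every recommendation can cite the rules
that fired. The numeric anchors are: EAU elevation threshold 3.0 ng/mL; a
*moderately elevated* PSA (up to 10 ng/mL) calls for a confirmatory repeat
after a few weeks; a confirmed elevation, or PSA above 10 ng/mL, calls for
urology referral; normal-PSA follow-up at 2-year intervals (EAU) and
regular screening every 2–4 years for ages 50–69 (AUA). Special cases
override the base rules: an elevated PSA during an active urinary tract
infection is deferred (treat, then repeat); an abnormal DRE is referred
regardless of PSA.

Two classes of parameters are deliberate **extensions**, flagged as such in
the rule file, because the codified subset must be total over all realistic
presentations: (a) behaviour outside the 50–69 band (no testing below the
band without risk factors, risk-adapted earlier offers from 45 (EAU) / 40
(AUA) for family history, BRCA carriage or African ancestry, no routine
testing above the band), and (b) the AUA elevation threshold, set to
4.0 ng/mL — the value most widely used in AUA-aligned practice — since the
codified sources state no single number. Because accuracy is graded as
concordance with *either* guideline, a case in the 3–4 ng/mL window where
the two engines disagree is handled the way real discordance is: both
recommendations are presented.

A regression case is wired through the tests: a 55-year-old with PSA
2.8 ng/mL must receive routine 2-year follow-up and never a confirmatory
repeat — the failure mode in which 2.8 is misread as "moderately elevated"
is reproduced only through the scripted replay backend, and the grader
classifies it as an unnecessary short-interval error.

## Retrieval-augmented architecture

The generation step is wrapped in a retrieval-augmented architecture so
that the same orchestration can drive a real language-model backend or the
deterministic engine:

* **Corpus and chunking.** Guideline text lives in markdown files with
  YAML front matter (`source: EAU|AUA`); the packaged fixture corpus
  paraphrases the rule statements above, each paragraph tagged with its
  rule identifier. Chunking packs paragraphs greedily to a 300-token
  target with 50 tokens of overlap (both configurable; the values are
  conventional for passage retrieval and unremarkable at fixture scale),
  and chunk ids are content hashes so indexing is reproducible.
* **Retrieval.** Lexical BM25 (k1 = 1.2, b = 0.75, non-negative
  Lucene-style idf, deterministic tie-break by chunk id) with source
  filtering, so EAU and AUA answers draw only on their own guideline.
  BM25 was chosen over embedding retrieval because it is deterministic,
  fully offline and oracle-checkable; an embedding backend can be slotted
  in through the same `chunk_index` surface. The default `k = 8` retrieves
  the whole per-source fixture corpus, which keeps the
  constrain-to-context property (no cited rule without a retrieved
  supporting passage) checkable end to end.
* **Prompting.** The prompt bundle applies four techniques: an expert
  clinician persona, chain-of-thought instruction, constraining the answer
  to the retrieved passages, and an example output structure (a strict
  JSON schema the response parser enforces). Every retrieved passage
  appears verbatim in the prompt.
* **Backends.** The backend contract is text in, text out. The *mock*
  backend parses the case block back out of the prompt and delegates to
  the rule engine — the pipeline is then exactly as accurate as the
  engine, which makes any deviation attributable. The *scripted* backend
  replays canned responses (including hallucinations) for failure-mode
  tests. No test requires a network.

Gate-refused cases short-circuit before retrieval: the trace records only
the CCI and gate stages, and tests assert the backend is never called.

## Evaluation harness

Grading is binomial — a response is correct if it is concordant with
either guideline's acceptable action (intervals must overlap where both
sides specify one) — and every incorrect response receives exactly one of
four error subtypes: *unnecessary, short interval*; *unnecessary, did not
require*; *missed, long interval*; *missed, failed to offer*. To compare
test timing across different action types, each test-offering action
carries an implied interval (offer now = 0 months; confirmatory repeat ≈
0.5–1.5 months; defer-and-repeat ≈ 1–3 months; routine = its stated
interval): a response strictly earlier than every acceptable option is an
unnecessary short-interval error, strictly later a missed long-interval
error. Whether "correct" should demand interval agreement at all is a
genuine design choice; `psarag` requires overlap, which is the stricter
reading.

Aggregation reports per-category counts, subtotals, totals and accuracy
with ratings (cases × raters) as denominators, plus pooled screening
(categories 1–2), follow-up (categories 3–5) and overall rows; subtotal
conservation is enforced by construction.

Fleiss kappa uses the standard pooled-proportion formula. When all cells
hold one single category, expected agreement is 1 and kappa is undefined;
the implementation raises an error rather than returning a number. For
confidence intervals the package uses a nonparametric item bootstrap
(default B = 1000, percentile interval, fixed seed): it is
distribution-free and reproducible. Published kappa intervals of width
~0.006 on 44 items are far narrower than any item-resampling scheme can
produce and are not a reproduction target. Accuracy arms can be compared
with a Student two-sample t test on the 0/1 outcomes (for comparability
with practice in the clinical literature) or a two-proportion z test, the
statistically conventional default here; on the shipped fixture both lead
to the same conclusion (p < .001).

### The reconstructed rating fixture

The published per-category error counts (three arms × five categories ×
four subtypes, 220 ratings per arm) ship as a CSV. Errors are filled into
(case, rater) slots lexicographically — arbitrary but fixed. Marginal
counts are exactly what the fixture guarantees; the true case/rater layout
is unknown, so agreement statistics on the *human* arms are not meaningful
and are not asserted anywhere. The LLM arm is the exception: its 10 errors
are 2 cases wrong in all 5 runs, so the layout is forced, the matrix is
unanimous per item, and Fleiss kappa is exactly 1.

## Synthetic cohort generator

The generator emulates the study conditions: 44 outpatient vignettes in
five categories — 11 screening-recommended, 9 screening-not-recommended, 9
normal-PSA follow-up, 8 elevated-PSA, 7 "other" — i.e. 20 screening and 24
follow-up cases. Category designs: category 1 samples eligible men 50–69
(about one in four a 45–49-year-old with a risk factor, exercising the
early-testing rules); category 2 alternates age-gate failures (73–85) with
life-expectancy failures (55–72 with a heavy comorbidity burden);
category 3 samples follow-up PSAs uniformly on 0.5–2.8 ng/mL; category 4
splits elevated PSAs into unconfirmed 3.2–9.5, confirmed repeats, and
values above 10; category 5 splits between UTI-spurious elevations,
comorbid elevations and abnormal-DRE-with-normal-PSA, roughly evenly since
the true within-category composition is unpublished. All randomness flows
from one seed through a single `set.seed` call with categories generated
in fixed order, so cohorts are bit-reproducible.

Gold labels are derived by running the rule engine on each generated case,
which keeps them internally consistent: the mock pipeline then scores 100%
by construction, and any deviation (a scripted hallucination, a degraded
rating profile) is attributable to the injected fault rather than to label
noise. The generator does not produce free-text clinical prose (the
`free_text` field is template-filled), does not model measurement noise in
PSA assays, and its case mix is a design choice rather than a sample from
any real population — so a perfect mock score demonstrates the pipeline's
internal consistency, not clinical accuracy on real patients.

One consequence of self-consistent gold labels: an all-correct rating
matrix has a single category and kappa is undefined there. Run-to-run
consistency of the pipeline is therefore measured on the *recommended
action labels* (items = cases, raters = runs, categories = actions), which
is unanimous with several categories present and yields kappa = 1 — the
meaningful formalisation of "the tool gives the same answer every run".

## Problem sizes and numerical notes

The shipped corpus is a two-document rule paraphrase (a dozen chunks), the
cohort 44 cases, bootstrap defaults B = 1000, and the property tests run
tens of seeded iterations; everything completes in seconds. Survival
values are clamped to [0, 1] against floating-point drift at extreme
scores; BM25 uses the non-negative idf variant so `min_score = 0` retains
all matches; interval comparisons use closed intervals, with equality
counting as overlap.

## Limitations

The engine encodes the rules relevant to PSA-testing decisions only — no
biopsy, imaging or risk-calculator pathways. The CCI itself is a blunt
life-expectancy instrument (additive comorbidity effects, 1980s cohort
calibration); the module boundary is designed so an alternative calculator
can be substituted, or the gate disabled. The fixture corpus is a
paraphrased rule subset, not the full guideline documents, and the mock
backend cannot exhibit the reasoning failures of a real language model —
those are injected, not emergent.
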