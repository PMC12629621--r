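---
source: AUA
section: Early detection of prostate cancer
---
Clinicians should engage in shared decision-making with people for whom
prostate cancer screening would be appropriate, proceeding based on the
person's values and preferences. For people aged 50 to 69 years, regular
prostate cancer screening with PSA every 2 to 4 years is recommended.
[rule:aua.routine_screening_interval] [rule:aua.routine_followup_interval]

It may be reasonable to begin prostate cancer screening earlier, at age 40
to 45 years, for people at increased risk of developing prostate cancer:
those of Black ancestry, carriers of germline mutations such as BRCA, and
those with a strong family history of prostate cancer.
[rule:aua.early_testing_risk_factors]

Routine PSA screening is not recommended for average-risk people under 50
years of age; the decision should remain individualised and shared.
[rule:aua.below_band_no_testing]

Do not offer routine PSA screening to people over the recommended age
range or with a life expectancy of less than ten years, in whom the
potential harms of screening outweigh the benefits; repeat testing of an
elevated PSA is unlikely to benefit patients with significant comorbidity.
[rule:aua.gate_no_testing] [rule:aua.over_band_no_testing]
[rule:aua.comorbid_elevated_no_benefit]

For people with a newly elevated PSA of up to 10 ng/mL, clinicians should
repeat the PSA test after a few weeks, before proceeding to secondary
evaluation, to confirm the elevation. [rule:aua.moderately_elevated_confirm_repeat]

A confirmed elevated PSA, or a markedly elevated PSA above 10 ng/mL,
should prompt referral to a urologist for evaluation with consideration of
further risk stratification. [rule:aua.confirmed_elevation_refer]
[rule:aua.psa_over_10_refer]

PSA should not be measured, or an elevated result should not be acted on,
during an active urinary tract infection: treat the infection and repeat
the test afterwards, as infection spuriously elevates PSA.
[rule:aua.uti_spurious_defer_repeat]

A suspicious or abnormal digital rectal examination warrants urology
referral irrespective of the PSA concentration.
[rule:aua.abnormal_dre_refer]
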