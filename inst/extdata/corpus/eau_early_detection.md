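---
source: EAU
section: Early detection of prostate cancer
---
Offer an individualised, risk-adapted strategy for the early detection of
prostate cancer to well-informed men aged 50 years and over with a good
performance status and a life expectancy of at least ten years. A baseline
serum PSA test should be offered after counselling on the potential risks
and benefits of testing. [rule:eau.offer_baseline_test]

Offer early PSA testing to well-informed men at elevated risk: men aged 45
years and over with a family history of prostate cancer or of African
ancestry, and carriers of BRCA2 germline mutations aged 40 years and over.
[rule:eau.early_testing_risk_factors]

The most commonly applied threshold for a suspicious PSA is 3.0 ng/mL and
above. For men whose PSA concentration is below 3.0 ng/mL, a risk-adapted
follow-up strategy applies: follow-up intervals of two years may be
considered for those at elevated risk, with testing postponed for those at
low risk. [rule:eau.routine_followup_interval]

In case of a moderately elevated PSA, up to 10 ng/mL, a repeated test after
a few weeks should be considered, under standardised conditions in the same
laboratory, to confirm the increase before any further investigation.
[rule:eau.moderately_elevated_confirm_repeat]

A confirmed elevated PSA, or a PSA concentration above 10 ng/mL, warrants
referral to a urologist for further risk stratification and assessment.
[rule:eau.confirmed_elevation_refer] [rule:eau.psa_over_10_refer]

Do not offer early detection PSA testing to men with a life expectancy of
less than ten years, based on age and comorbidity assessment such as the
Charlson Comorbidity Index; in such men further or repeat testing of an
elevated PSA is unlikely to be beneficial. [rule:eau.gate_no_testing]
[rule:eau.comorbid_elevated_no_benefit] [rule:eau.over_band_no_testing]

PSA-based early detection is not recommended for men below the risk-adapted
starting ages; routine testing of young men without risk factors should not
be offered. [rule:eau.below_band_no_testing]

A PSA concentration that is spuriously elevated, for example during an
active urinary tract infection, should not prompt investigation: treat the
infection first and repeat the PSA afterwards.
[rule:eau.uti_spurious_defer_repeat]

An abnormal digital rectal examination is an indication for referral to a
urologist even when the PSA concentration is normal, as it is associated
with higher-grade disease. [rule:eau.abnormal_dre_refer]
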