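# Versioned rule file for the dual-guideline PSA recommendation engine.
# This is a codified subset of the EAU and AUA early-detection rules:
# the numeric anchors (EAU >= 3.0 ng/mL threshold, "moderately elevated"
# up to 10 ng/mL with a confirmatory repeat after a few weeks, EAU 2-year
# follow-up interval, AUA 2-4-year screening interval for ages 50-69) are
# guideline-anchored; entries marked `extension: true` cover presentations
# the codified subset must still answer (men outside the core age band,
# risk-adapted early testing) and are explicit, editable policy choices.
version: 1
eau:
  psa_elevated_threshold: 3.0      # ng/mL
  moderately_elevated_max: 10.0    # ng/mL
  routine_interval_months: [24, 24]
  screening_age_min: 50
  screening_age_max: 69
  early_risk_age_min: 45           # extension: risk-adapted earlier offer
  shared_decision_age: 50
aua:
  psa_elevated_threshold: 4.0      # ng/mL; extension (not stated in source)
  moderately_elevated_max: 10.0
  routine_interval_months: [24, 48]
  screening_age_min: 50
  screening_age_max: 69
  early_risk_age_min: 40           # extension: risk-adapted earlier offer
  shared_decision_always: true
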