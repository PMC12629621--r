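# Original Charlson comorbidity weights (1/2/3/6 tiers).
# Editable: substitute an alternative weight set without touching code.
weights:
  myocardial_infarction: 1
  congestive_heart_failure: 1
  peripheral_vascular_disease: 1
  cerebrovascular_disease: 1
  dementia: 1
  chronic_pulmonary_disease: 1
  rheumatic_disease: 1
  peptic_ulcer_disease: 1
  mild_liver_disease: 1
  diabetes_uncomplicated: 1
  diabetes_with_complications: 2
  hemiplegia: 2
  renal_disease: 2
  any_malignancy: 2
  leukemia: 2
  lymphoma: 2
  moderate_severe_liver_disease: 3
  metastatic_solid_tumor: 6
  aids: 6
  none: 0
# When the severe form (key) is coded together with the milder form (value)
# of the same organ system, only the severe weight counts.
supersedes:
  diabetes_with_complications: diabetes_uncomplicated
  moderate_severe_liver_disease: mild_liver_disease
  metastatic_solid_tumor: any_malignancy
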