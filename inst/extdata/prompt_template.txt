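{{persona}}

Guideline: {{guideline}}

Patient case (structured record):
<<CASE>>
{{case_json}}
<<END CASE>>

Retrieved guideline context (answer ONLY from these passages):
{{context}}

{{reasoning}}

Example output structure:
{{output_schema}}
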