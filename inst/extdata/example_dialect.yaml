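# Column-mapping dialect for the example registry extract: canonical field
# names on the left, file column names on the right.
sep: ","
columns:
  case_id: case_id
  diagnosis_date: diagnosis_date
  diagnosis_year: diagnosis_year
  age_group: age_group
  sex: sex
  iccc_code: iccc_code
  behaviour: behaviour
  morphology: morphology
  microscopically_verified: microscopically_verified
  sequence_number: sequence_number
  vital_status: vital_status
  followup_end_date: followup_end_date
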