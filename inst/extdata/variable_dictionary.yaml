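- variable: driving_license
  role: evidence
  states: ["Valid", "Invalid", "Other"]
- variable: age_band
  role: influential
  states: ["<25", "25-40", "41-60", ">60", "Unknown"]
- variable: gender
  role: influential
  states: ["Men", "Women", "Unknown"]
- variable: right_of_way_violation
  role: objective_behavior
  states: ["No", "Yes", "Unknown"]
- variable: speed_infringement
  role: objective_behavior
  states: ["No", "Yes", "Unknown"]
- variable: other_infringements
  role: objective_behavior
  states: ["No", "Yes", "Unknown"]
- variable: distraction
  role: objective_behavior
  states: ["No", "Technology", "Other", "Unknown"]
- variable: accident_type
  role: objective_accident
  states: ["Collision", "RunOver", "Other"]
- variable: accident_severity
  role: objective_accident
  states: ["NoneMild", "SeriousDeath"]
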