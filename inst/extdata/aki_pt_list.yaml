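# Default Preferred Term list for identifying acute kidney injury events,
# in the style of the standardized MedDRA query for acute renal failure.
# Replace with a licensed MedDRA SMQ export for production analyses.
aki_pts:
  - Acute kidney injury
  - Renal failure
  - Renal failure acute
  - Renal impairment
  - Anuria
  - Oliguria
  - Azotaemia
  - Blood creatinine increased
  - Blood creatinine abnormal
  - Glomerular filtration rate decreased
  - Hypercreatininaemia
  - Nephropathy toxic
  - Renal tubular necrosis
  - Prerenal failure
  - Dialysis
  - Haemodialysis
  - Continuous haemodiafiltration
  - Oedema due to renal disease
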