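# Template mapping from a raw deposited IST-3 export to the analysis schema.
#
# The deposited dataset's raw field names and level codes are defined by its
# data dictionary, which this package does not bundle; the `columns` keys
# below are placeholders that MUST be checked and edited against that
# dictionary before use. `values` recodes raw level codes to the schema's
# levels; raw values without an entry pass through unchanged.
columns:
  patient_id: patient_id
  treatment: treatment
  outcome: outcome
  age: age
  sex: sex
  livealone_rand: lived_alone
  infarct: ischemic_change
  antiplat_rand: antiplatelet
  atrialfib_rand: atrial_fibrillation
  sbprand: sbp
  dbprand: dbp
  weight: weight
  gcs_eye_rand: gcs_eye
  gcs_motor_rand: gcs_motor
  gcs_verbal_rand: gcs_verbal
  gcs_score_rand: gcs_total
  nihss: nihss
  stroketype: stroke_subtype
values:
  treatment:
    "0": control
    "1": treated
  sex:
    F: Female
    M: Male
  lived_alone:
    "1": "Yes"
    "0": "No"
  antiplatelet:
    "1": "Yes"
    "0": "No"
  atrial_fibrillation:
    "1": "Yes"
    "0": "No"
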