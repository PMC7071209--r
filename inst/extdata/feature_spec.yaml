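# Patient-level feature roster for the PPGR design matrix.
# blocks: patient_numeric (anthropometrics + biochemistry), obstetric counts,
# history (binary), questionnaire (ordinal 0/1/2, assessed before and during
# pregnancy), group (GDM vs control).
variables:
  - {name: group, block: patient, type: categorical, levels: [GDM, control]}
  - {name: age, block: patient_numeric, type: numeric}
  - {name: weight, block: patient_numeric, type: numeric}
  - {name: bmi, block: patient_numeric, type: numeric}
  - {name: gestational_age, block: patient_numeric, type: numeric}
  - {name: bp_systolic, block: patient_numeric, type: numeric}
  - {name: bp_diastolic, block: patient_numeric, type: numeric}
  - {name: ogtt_fasting, block: patient_numeric, type: numeric}
  - {name: ogtt_1h, block: patient_numeric, type: numeric}
  - {name: ogtt_2h, block: patient_numeric, type: numeric}
  - {name: hba1c, block: patient_numeric, type: numeric}
  - {name: fasting_insulin, block: patient_numeric, type: numeric}
  - {name: cholesterol, block: patient_numeric, type: numeric}
  - {name: hdl, block: patient_numeric, type: numeric}
  - {name: ldl, block: patient_numeric, type: numeric}
  - {name: triglycerides, block: patient_numeric, type: numeric}
  - {name: leptin, block: patient_numeric, type: numeric}
  - {name: n_pregnancies, block: obstetric, type: numeric}
  - {name: n_abortions, block: obstetric, type: numeric}
  - {name: n_deliveries, block: obstetric, type: numeric}
  - {name: n_miscarriages, block: obstetric, type: numeric}
  - {name: gdm_history, block: history, type: binary}
  - {name: pcos, block: history, type: binary}
  - {name: igt_history, block: history, type: binary}
  - {name: family_diabetes, block: history, type: binary}
  - {name: hypertension, block: history, type: binary}
  - {name: oc_pills, block: history, type: binary}
  - {name: smoking, block: history, type: binary}
  - {name: fruits_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: fruits_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: sweets_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: sweets_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: meat_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: meat_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: dairy_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: dairy_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: bread_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: bread_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: vegetables_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: vegetables_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: soda_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: soda_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: activity_before, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
  - {name: activity_during, block: questionnaire, type: ordinal, levels: [0, 1, 2]}
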