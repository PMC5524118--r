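# Editable case-definition code lists for acute cardiovascular event
# surveillance. ED/hospitalization events match on primary-diagnosis codes
# (ICD-9-CM style, `ed_hosp_codes`); deaths match on underlying-cause codes
# (ICD-10 style, `death_codes`). Matching is prefix-based on dot-stripped
# codes, so "410" covers 410.00-410.92.
#
# These defaults are a plausible starting point for demonstration and
# simulation; production surveillance should review and replace them.
ami:
  acute_myocardial_infarction:
    ed_hosp_codes: ["410"]
    death_codes: ["I21", "I22"]
stroke:
  acute_ischemic_cerebral_infarction:
    ed_hosp_codes: ["433", "434"]
    death_codes: ["I63"]
  acute_hemorrhagic_stroke:
    ed_hosp_codes: ["430", "431", "432"]
    death_codes: ["I60", "I61", "I62"]
  acute_ill_defined_cerebrovascular:
    ed_hosp_codes: ["436"]
    death_codes: ["I64"]
  other_cerebrovascular:
    ed_hosp_codes: []
    death_codes: ["I67", "I69"]
symptomatic_precursor:
  other_acute_subacute_ischemic_heart_disease:
    ed_hosp_codes: ["411"]
    death_codes: ["I24"]
  stable_angina_pectoris:
    ed_hosp_codes: ["413"]
    death_codes: ["I20"]
  transient_ischemic_attack:
    ed_hosp_codes: ["435"]
    death_codes: ["G45"]
other_cvd:
  heart_failure:
    ed_hosp_codes: ["428"]
    death_codes: ["I50"]
  abdominal_aortic_aneurysm:
    ed_hosp_codes: ["4413", "4414"]
    death_codes: ["I713", "I714"]
  atheroembolism:
    ed_hosp_codes: ["4450", "4458"]
    death_codes: ["I75"]
  atherosclerosis_peripheral_artery_disease:
    ed_hosp_codes: ["440", "4439"]
    death_codes: ["I70", "I739"]
  hypertension_without_heart_failure:
    ed_hosp_codes: ["401", "402", "403", "404"]
    death_codes: ["I10", "I11", "I12", "I13"]
  cardiac_arrest:
    ed_hosp_codes: ["4275"]
    death_codes: ["I46"]
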