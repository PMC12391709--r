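# Default trigger rule set: 24 rules over four categories
# (laboratory L, antidote A, symptom S, treatment T).
# All printed thresholds are strict inequalities ("<", ">").
#
# Upper limits of normal used by uln_multiple thresholds. These are
# site-configurable reference values; override them here to match local
# laboratory reference ranges.
uln:
  alt: 40              # U/L
  ast: 40              # U/L
  total_bilirubin: 21  # umol/L
  alp: 125             # U/L

triggers:
  - id: L1
    category: laboratory
    description: "Absolute eosinophil count > 0.3 x 10^9/L"
    condition:
      type: threshold
      analyte: eosinophils_abs
      comparator: ">"
      bound: 0.3
  - id: L2
    category: laboratory
    description: "Platelet count < 50 x 10^9/L"
    condition:
      type: threshold
      analyte: platelets
      comparator: "<"
      bound: 50
  - id: L3
    category: laboratory
    description: "Leucocyte count < 3 x 10^9/L"
    condition:
      type: threshold
      analyte: leukocytes
      comparator: "<"
      bound: 3
  - id: L4
    category: laboratory
    description: >-
      ALT or AST > 3x ULN, or total bilirubin and ALP both > 2x ULN
    condition:
      type: any
      of:
        - {type: threshold, analyte: alt, comparator: ">", uln_multiple: 3}
        - {type: threshold, analyte: ast, comparator: ">", uln_multiple: 3}
        - type: all
          of:
            - {type: threshold, analyte: total_bilirubin, comparator: ">", uln_multiple: 2}
            - {type: threshold, analyte: alp, comparator: ">", uln_multiple: 2}
  - id: L5
    category: laboratory
    description: "BUN or serum creatinine > 2x the first in-stay (baseline) value"
    condition:
      type: baseline_ratio
      analytes: [bun, creatinine]
      ratio: 2
  - id: L6
    category: laboratory
    description: "Hemoglobin below the age- and sex-specific lower bound"
    condition:
      type: threshold
      analyte: hemoglobin
      comparator: "<"
      strata:
        - {age_min: 0.5, age_max: 5, bound: 110}
        - {age_min: 5, age_max: 12, bound: 115}
        - {age_min: 12, age_max: 15, bound: 120}
        - {age_min: 15, sex: male, bound: 120}
        - {age_min: 15, sex: female, bound: 110}
  - id: L7
    category: laboratory
    description: "Blood sodium > 145 mmol/L"
    condition:
      type: threshold
      analyte: sodium
      comparator: ">"
      bound: 145
  - id: A1
    category: antidote
    description: "Use of vasopressors (e.g. norepinephrine, dobutamine, ephedrine)"
    condition: {type: drug_class, class: vasopressor}
  - id: A2
    category: antidote
    description: "Use of antiemetics (e.g. metoclopramide, ondansetron)"
    condition: {type: drug_class, class: antiemetic}
  - id: A3
    category: antidote
    description: "Use of antidiarrheals (e.g. loperamide, montmorillonite powder)"
    condition: {type: drug_class, class: antidiarrheal}
  - id: A4
    category: antidote
    description: "Use of hepatoprotectives (e.g. glutathione, silymarin)"
    condition: {type: drug_class, class: hepatoprotective}
  - id: A5
    category: antidote
    description: "Use of laxatives or stool-softeners (e.g. lactulose, senna)"
    condition: {type: drug_class, class: laxative}
  - id: A6
    category: antidote
    description: "Use of antihistamines (e.g. loratadine, cetirizine)"
    condition: {type: drug_class, class: antihistamine}
  - id: S1
    category: symptom
    description: "Bleeding of any site"
    condition:
      type: symptom_set
      terms: [rectal_bleeding, nosebleed, eye_bleeding, intraabdominal_bleeding,
              hemorrhage, bleeding_tendency, severe_bleeding, hematemesis,
              gi_bleeding, subcutaneous_bleeding, urinary_bleeding]
  - id: S2
    category: symptom
    description: "Nausea, vomiting, abdominal pain, diarrhea, bloating"
    condition:
      type: symptom_set
      terms: [nausea, vomiting, abdominal_pain, diarrhea, bloating]
  - id: S3
    category: symptom
    description: "Arthralgia or pain in bone, jaw, back, neck or chest"
    condition:
      type: symptom_set
      terms: [arthralgia, bone_pain, jaw_pain, back_pain, neck_pain, chest_pain]
  - id: S4
    category: symptom
    description: "Flushing, rash, itching, hives, eczema"
    condition:
      type: symptom_set
      terms: [flushing, hot_flush, rash, itching, hives, eczema]
  - id: S5
    category: symptom
    description: "Peripheral edema, puffiness, edema or swelling"
    condition:
      type: symptom_set
      terms: [peripheral_edema, puffiness, edema, swelling]
  - id: S6
    category: symptom
    description: "Dizziness, headaches"
    condition:
      type: symptom_set
      terms: [dizziness, headache]
  - id: S7
    category: symptom
    description: "Neuropsychiatric symptoms (insomnia, vertigo, fainting, neuralgia, ...)"
    condition:
      type: symptom_set
      terms: [insomnia, anxiety, transient_amnesia, depression, drowsiness,
              vertigo, upright_vertigo, fainting, loss_of_consciousness,
              numbness, floating_sensation, neuralgia]
  - id: S8
    category: symptom
    description: "Kidney injury or urinary abnormality"
    condition:
      type: symptom_set
      terms: [kidney_injury, acute_kidney_injury, oliguria, anuria,
              acute_tubular_necrosis, tubular_dysfunction, proteinuria,
              hematuria, chronic_kidney_damage]
  - id: T1
    category: treatment
    description: "Transfer to ICU"
    condition: {type: intervention, kind: icu_transfer}
  - id: T2
    category: treatment
    description: "Salvage / rescue procedure"
    condition: {type: intervention, kind: salvage}
  - id: T3
    category: treatment
    description: "Abrupt cessation of a target medication"
    condition: {type: abrupt_cessation}
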