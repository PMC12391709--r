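# Controlled symptom vocabulary: canonical codes with free-text aliases.
# Event terms are normalized (lower case, collapsed whitespace) and matched
# against codes and aliases; unknown terms are rejected by the cohort reader.
terms:
  - code: rectal_bleeding
    aliases: ["rectal bleeding"]
  - code: nosebleed
    aliases: ["nosebleeds", "epistaxis"]
  - code: eye_bleeding
    aliases: ["eye bleeding", "fundus bleeding"]
  - code: intraabdominal_bleeding
    aliases: ["intra-abdominal bleeding"]
  - code: hemorrhage
    aliases: ["haemorrhage", "bleeding"]
  - code: bleeding_tendency
    aliases: ["bleeding tendencies"]
  - code: severe_bleeding
    aliases: ["severe bleeding"]
  - code: hematemesis
    aliases: ["vomiting blood"]
  - code: gi_bleeding
    aliases: ["gastrointestinal bleeding"]
  - code: subcutaneous_bleeding
    aliases: ["subcutaneous bleeding"]
  - code: urinary_bleeding
    aliases: ["urinary-tract bleeding", "urinary tract bleeding", "hematuria bleeding"]
  - code: nausea
    aliases: []
  - code: vomiting
    aliases: []
  - code: abdominal_pain
    aliases: ["abdominal pain", "stomach ache"]
  - code: diarrhea
    aliases: ["diarrhoea"]
  - code: bloating
    aliases: ["abdominal distension"]
  - code: arthralgia
    aliases: ["joint pain"]
  - code: bone_pain
    aliases: ["bone pain"]
  - code: jaw_pain
    aliases: ["jaw pain"]
  - code: back_pain
    aliases: ["back pain"]
  - code: neck_pain
    aliases: ["neck pain"]
  - code: chest_pain
    aliases: ["chest pain"]
  - code: flushing
    aliases: ["facial flushing"]
  - code: hot_flush
    aliases: ["hot flushes"]
  - code: rash
    aliases: []
  - code: itching
    aliases: ["pruritus"]
  - code: hives
    aliases: ["urticaria"]
  - code: eczema
    aliases: []
  - code: peripheral_edema
    aliases: ["peripheral oedema", "lower-extremity edema", "lower extremity edema"]
  - code: puffiness
    aliases: ["puffy"]
  - code: edema
    aliases: ["oedema", "angioedema", "retinal edema", "facial edema"]
  - code: swelling
    aliases: ["fluid retention"]
  - code: dizziness
    aliases: []
  - code: headache
    aliases: ["headaches"]
  - code: insomnia
    aliases: []
  - code: anxiety
    aliases: []
  - code: transient_amnesia
    aliases: ["transient amnesia"]
  - code: depression
    aliases: []
  - code: drowsiness
    aliases: ["somnolence"]
  - code: vertigo
    aliases: []
  - code: upright_vertigo
    aliases: ["upright vertigo"]
  - code: fainting
    aliases: ["syncope"]
  - code: loss_of_consciousness
    aliases: ["loss of consciousness", "unconsciousness"]
  - code: numbness
    aliases: []
  - code: floating_sensation
    aliases: ["floating sensation"]
  - code: neuralgia
    aliases: ["neuropathy"]
  - code: kidney_injury
    aliases: ["kidney injury", "renal injury"]
  - code: acute_kidney_injury
    aliases: ["acute kidney injury"]
  - code: oliguria
    aliases: []
  - code: anuria
    aliases: []
  - code: acute_tubular_necrosis
    aliases: ["acute tubular necrosis"]
  - code: tubular_dysfunction
    aliases: ["tubular dysfunction"]
  - code: proteinuria
    aliases: []
  - code: hematuria
    aliases: ["haematuria"]
  - code: chronic_kidney_damage
    aliases: ["chronic kidney damage"]
  - code: muscle_soreness
    aliases: ["muscle soreness", "myalgia"]
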