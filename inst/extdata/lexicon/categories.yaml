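# Keyword -> category map for the 14 symptom categories.
# Keys are category names; values are single-word keywords matched against
# normalized (lowercased, accent-folded) query tokens.  A keyword may appear
# under more than one category: categories are not mutually exclusive.
# English plus a small set of French and Spanish colloquial equivalents.
bleeding:
  - bleeding
  - bleed
  - spotting
  - haemorrhage
  - hemorrhage
  - sangrado
  - saignement
bloating:
  - bloating
  - bloated
  - distension
  - distended
  - hinchazon
  - ballonnement
diagnostics:
  - ultrasound
  - scan
  - biopsy
  - ca125
  - mri
  - smear
  - colonoscopy
  - hysteroscopy
  - ecografia
  - echographie
fatigue:
  - fatigue
  - tired
  - tiredness
  - exhaustion
  - fatiga
gastrointestinal:
  - indigestion
  - constipation
  - diarrhoea
  - diarrhea
  - nausea
  - reflux
  - stomach
  - bowel
  - vomiting
  - estrenimiento
  - nausee
gynaecological:
  - ovarian
  - ovary
  - ovaries
  - endometrial
  - endometriosis
  - uterus
  - uterine
  - cervix
  - fibroid
  - ovario
  - uterus
menopause:
  - menopause
  - menopausal
  - perimenopause
  - hrt
  - flushes
  - menopausia
nutrition:
  - diet
  - appetite
  - nutrition
  - vitamin
  - dieta
other conditions:
  - diabetes
  - thyroid
  - anaemia
  - anemia
  - migraine
  - asthma
pain:
  - pain
  - ache
  - cramp
  - cramps
  - painful
  - douleur
  - dolor
pelvic organs:
  - pelvis
  - bladder
  - abdomen
  - abdominal
  - pelvis
symptoms:
  - symptom
  - symptoms
  - sintomas
  - symptome
  - symptomes
urinary:
  - urinary
  - urine
  - urination
  - urgency
  - incontinence
  - cystitis
  - uti
  - orina
vagina or pelvic organs:
  - vagina
  - vaginal
  - vulva
  - discharge
  - pelvic
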