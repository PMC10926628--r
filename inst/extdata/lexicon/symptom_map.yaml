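# Synthetic stand-in for the (unpublished) supplementary mapping from the
# 20 questionnaire symptoms to indicative query terms.  A patient counts as
# having "searched for" a symptom when at least one filtered query contains
# at least one mapped term (single words match tokens; multi-word terms
# match consecutive normalized words).
pelvic pain: [pelvic pain, pelvic ache, dolor pelvico, douleur pelvienne]
bloating: [bloating, bloated, distension, hinchazon, ballonnement]
post-menopausal bleeding: [post menopausal bleeding, bleeding after menopause]
irregular bleeding: [irregular bleeding, spotting, bleeding between periods]
heavy periods: [heavy periods, heavy bleeding, tranexamic]
dyspareunia: [painful intercourse, dyspareunia, pain during sex]
weight loss: [weight loss, losing weight]
appetite loss: [appetite loss, loss of appetite, no appetite]
constipation: [constipation, laxative, estrenimiento]
diarrhoea: [diarrhoea, diarrhea, loose stools]
nausea: [nausea, nauseous, vomiting, nausee]
urgency: [urinary urgency, urgency]
frequency: [urinary frequency, urinating often]
incontinence: [incontinence, leaking urine]
fatigue: [fatigue, tired, tiredness, exhaustion, fatiga]
back pain: [back pain, backache]
abdominal swelling: [swollen abdomen, abdominal distension, swollen stomach]
early satiety: [early satiety, feeling full quickly, full quickly]
vaginal discharge: [vaginal discharge, discharge]
hot flushes: [hot flushes, flushes, night sweats]
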