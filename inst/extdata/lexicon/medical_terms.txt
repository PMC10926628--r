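# One medical phrase per line (symptoms, diseases, drugs); words of each
# phrase are matched independently against query tokens after normalization.
# Lines starting with '#' are comments.
pelvic pain
abdominal pain
back pain
stomach ache
pain relief
period pain
painful intercourse
cramps
bloating
bloated stomach
abdominal distension
post menopausal bleeding
vaginal bleeding
irregular bleeding
heavy periods
spotting between periods
haemorrhage
ovarian cyst
ovarian cancer
endometrial cancer
cervical cancer
endometriosis
uterine fibroid
prolapsed uterus
cervix
menopause
perimenopause symptoms
hot flushes
hrt side effects
urinary tract infection
urinary incontinence
urinary urgency
urinary frequency
blood in urine
cystitis
uti treatment
constipation
diarrhoea
diarrhea
indigestion
acid reflux
nausea
vomiting
bowel habit change
loss of appetite
appetite loss
weight loss
unexplained weight loss
fatigue
tiredness
exhaustion
vaginal discharge
vulva itching
pelvic ultrasound
transvaginal scan
ca125 blood test
mri scan
biopsy
smear test
colonoscopy
hysteroscopy
early satiety
feeling full quickly
swollen abdomen
club foot
diabetes
type 2 diabetes
thyroid problems
anaemia
iron deficiency anemia
migraine
asthma
hypertension
eczema
psoriasis
gallstones
kidney stones
irritable bowel syndrome
coeliac disease
diverticulitis
gastritis
hernia
arthritis
osteoporosis
depression
anxiety
insomnia
vertigo
sciatica
shingles
gout
paracetamol
ibuprofen
omeprazole
buscopan
laxative
mebeverine
tranexamic acid
codeine
naproxen
douleur pelvienne
saignement vaginal
ballonnement abdominal
fatigue chronique
symptome menopause
dolor pelvico
sangrado vaginal
hinchazon abdominal
sintomas menopausia
estrenimiento
nausee
dieta
vitamin d deficiency
bladder problems
bleed
cramp
diet plan
distended abdomen
echographie pelvienne
ecografia pelvica
fatiga cronica
hemorrhage
nutrition advice
orina con sangre
ovaries
ovario
ovary pain
pelvis
symptom checker
symptomes menopause
tired all the time
urination at night
vagina
hypothyroidism
hyperthyroidism
osteoarthritis
rheumatoid arthritis
fibromyalgia
polycystic ovary syndrome
pelvic inflammatory disease
bacterial vaginosis
thrush
adenomyosis
lichen sclerosus
chronic fatigue syndrome
glandular fever
pneumonia
bronchitis
sinusitis
tonsillitis
appendicitis
pancreatitis
hepatitis
cirrhosis
crohn disease
ulcerative colitis
peptic ulcer
barrett oesophagus
deep vein thrombosis
pulmonary embolism
atrial fibrillation
angina
heart failure
stroke
epilepsy
multiple sclerosis
parkinson disease
dementia
glaucoma
cataract
macular degeneration
tinnitus
labyrinthitis
carpal tunnel syndrome
plantar fasciitis
tennis elbow
frozen shoulder
slipped disc
scoliosis
osteomyelitis
cellulitis
impetigo
rosacea
vitiligo
alopecia
lupus
sarcoidosis
amyloidosis
haemochromatosis
addison disease
cushing syndrome
acromegaly
prolactinoma
mastitis
lymphoedema
varicose veins
haemorrhoids
anal fissure
bowel obstruction
gastroenteritis
norovirus
salmonella
lyme disease
malaria
tuberculosis
hiv
hepatitis b
hepatitis c
measles
mumps
rubella
chickenpox
whooping cough
scarlet fever
sepsis
meningitis
encephalitis
vitamin b12 deficiency
folate deficiency
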