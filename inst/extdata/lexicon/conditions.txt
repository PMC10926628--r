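# Synthetic stand-in for the (unpublished) 5521-entry medical-condition
# list used by the engagement filter.  One condition per line; multi-word
# conditions are matched as consecutive normalized words.  Replace with a
# full list via read_lexicon() for production use.
diabetes
type 2 diabetes
hypertension
asthma
eczema
psoriasis
migraine
anaemia
iron deficiency anemia
thyroid problems
hypothyroidism
hyperthyroidism
gallstones
kidney stones
irritable bowel syndrome
coeliac disease
diverticulitis
gastritis
acid reflux
hernia
arthritis
osteoarthritis
rheumatoid arthritis
osteoporosis
fibromyalgia
depression
anxiety
insomnia
vertigo
sciatica
shingles
gout
endometriosis
uterine fibroid
ovarian cyst
polycystic ovary syndrome
pelvic inflammatory disease
urinary tract infection
cystitis
bacterial vaginosis
thrush
prolapsed uterus
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
vitamin d deficiency
vitamin b12 deficiency
folate deficiency
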