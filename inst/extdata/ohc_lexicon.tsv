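surface	concept_id	category
lorazepam	lorazepam	drug
amitriptyline	amitriptyline	drug
gabapentin	gabapentin	drug
methylphenidate	methylphenidate	drug
quetiapine	quetiapine	drug
pregabalin	pregabalin	drug
celecoxib	celecoxib	drug
buprenorphine	buprenorphine	drug
natalizumab	natalizumab	drug
clopidogrel	clopidogrel	drug
levonorgestrel	levonorgestrel	drug
levofloxacin	levofloxacin	drug
anxiety	anxiety	indication
depression	depression	indication
epilepsy	epilepsy	indication
seizures	seizures	indication
seizure	seizures	indication
postherpetic neuralgia	postherpetic_neuralgia	indication
pain	pain	indication
acute pain	acute_pain	indication
nerve pain	neuropathic_pain	indication
neuropathic pain	neuropathic_pain	indication
neuropathy	neuropathy	indication
diabetic peripheral neuropathy	diabetic_peripheral_neuropathy	indication
insomnia	sleep_disorder_insomnia	indication
sleep disorder	sleep_disorder_insomnia	indication
sleeplessness	sleep_disorder_insomnia	indication
migraine	migraine	indication
migraines	migraine	indication
headache	headaches	indication
headaches	headaches	indication
panic attack	panic_attacks	indication
panic attacks	panic_attacks	indication
fibromyalgia	fibromyalgia	indication
multiple sclerosis	multiple_sclerosis	indication
bipolar disorder	bipolar_disorder	indication
mania	mania	indication
schizophrenia	schizophrenia	indication
mental disorders	mental_disorders	indication
adhd	attention_deficit_hyperactivity_disorder	indication
attention deficit hyperactivity disorder	attention_deficit_hyperactivity_disorder	indication
osteoarthritis	osteoarthritis	indication
rheumatoid arthritis	rheumatoid_arthritis	indication
juvenile rheumatoid arthritis	juvenile_rheumatoid_arthritis	indication
arthritis	arthritis	indication
dysmenorrhea	dysmenorrhea	indication
contraception	contraception	indication
overdose	overdose	indication
drug abuse	drug_abuse	indication
addiction	addiction	indication
spinal cord injury	spinal_cord_injury	indication
partial onset seizures	partial_onset_seizures	indication
fatigue	fatigue	indication
stress disorder	stress_disorder	indication
nausea	nausea	indication
common cold	common_cold	indication
stroke	stroke	indication
tachycardia	tachycardia	indication
chills	chills	indication
hyperventilating	hyperventilating	indication
cystitis	cystitis	indication
numbness	numbness	indication
spasms	spasms	indication
swelling	swelling	indication
heartburn	heartburn	indication
restless legs syndrome	restless_legs_syndrome	indication
menopause	menopause	indication
irritable bowel syndrome	irritable_bowel_syndrome	indication
carcinoma	carcinoma	indication
gastritis	gastritis	indication
angina	angina	indication
cancer	cancer	indication
autism	autism	indication
apnea	apnea	indication
diabetes	diabetes	indication
tumors	tumors	indication
mood control	mood_control	indication
anger management	anger_management	indication
paranoia	paranoia	indication
agitation	agitation	indication
hallucinations	hallucinations	indication
dyskinesia	dyskinesia	indication
dizziness	dizziness	indication
palpitations	palpitations	indication
allergy	allergy	indication
psychosis	psychosis	indication
hypothyroidism	hypothyroidism	indication
hives	hives	indication
shingles	shingles	indication
influenza	influenza	indication
neuralgia	neuralgia	indication
paresthesia	paresthesia	indication
spondylitis	spondylitis	indication
tendonitis	tendonitis	indication
hematuria	hematuria	indication
infection	infection	indication
asthma	asthma	indication
blood clots	antiplatelet_agent	indication
bacterial infection	broad_spectrum_antibiotic	indication
birth control	contraception	indication
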