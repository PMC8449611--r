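{
  "lorazepam": {
    "approved": ["anxiety", "depression"],
    "synonyms": {
      "anxious": "anxiety",
      "anxiety disorder": "anxiety",
      "depressed": "depression"
    }
  },
  "amitriptyline": {
    "approved": ["depression"],
    "synonyms": {}
  },
  "gabapentin": {
    "approved": ["epilepsy", "postherpetic_neuralgia", "seizures"],
    "synonyms": {
      "seizure": "seizures",
      "epileptic seizures": "seizures",
      "postherpetic neuralgia": "postherpetic_neuralgia"
    }
  },
  "methylphenidate": {
    "approved": ["attention_deficit_hyperactivity_disorder"],
    "synonyms": {
      "adhd": "attention_deficit_hyperactivity_disorder",
      "attention deficit hyperactivity disorder": "attention_deficit_hyperactivity_disorder",
      "attention deficit disorder": "attention_deficit_hyperactivity_disorder"
    }
  },
  "quetiapine": {
    "approved": ["bipolar_disorder", "depression", "mania", "mental_disorders", "schizophrenia"],
    "synonyms": {
      "bipolar": "bipolar_disorder",
      "bipolar disorder": "bipolar_disorder",
      "bipolar i disorder": "bipolar_disorder",
      "bipolar ii disorder": "bipolar_disorder",
      "manic": "mania",
      "mental disorder": "mental_disorders",
      "schizophrenic": "schizophrenia"
    }
  },
  "pregabalin": {
    "approved": ["spinal_cord_injury", "diabetic_peripheral_neuropathy", "fibromyalgia", "neuropathic_pain", "partial_onset_seizures", "postherpetic_neuralgia"],
    "synonyms": {
      "spinal cord injury": "spinal_cord_injury",
      "diabetic peripheral neuropathy": "diabetic_peripheral_neuropathy",
      "diabetic neuropathy": "diabetic_peripheral_neuropathy",
      "nerve pain": "neuropathic_pain",
      "neuropathic pain": "neuropathic_pain",
      "partial onset seizures": "partial_onset_seizures",
      "shingles pain": "postherpetic_neuralgia"
    }
  },
  "celecoxib": {
    "approved": ["acute_pain", "dysmenorrhea", "juvenile_rheumatoid_arthritis", "osteoarthritis", "pain", "rheumatoid_arthritis"],
    "synonyms": {
      "acute pain": "acute_pain",
      "menstrual cramps": "dysmenorrhea",
      "juvenile rheumatoid arthritis": "juvenile_rheumatoid_arthritis",
      "rheumatoid arthritis": "rheumatoid_arthritis"
    }
  },
  "buprenorphine": {
    "approved": ["overdose", "pain", "drug_abuse"],
    "synonyms": {
      "drug abuse": "drug_abuse",
      "opioid dependence": "drug_abuse",
      "drug addiction": "drug_abuse"
    }
  },
  "natalizumab": {
    "approved": ["multiple_sclerosis"],
    "synonyms": {
      "multiple sclerosis": "multiple_sclerosis",
      "ms": "multiple_sclerosis"
    }
  },
  "clopidogrel": {
    "approved": ["antiplatelet_agent"],
    "synonyms": {
      "antiplatelet agent": "antiplatelet_agent",
      "blood clots": "antiplatelet_agent"
    }
  },
  "levonorgestrel": {
    "approved": ["contraception"],
    "synonyms": {
      "birth control": "contraception"
    }
  },
  "levofloxacin": {
    "approved": ["broad_spectrum_antibiotic"],
    "synonyms": {
      "broad spectrum antibiotic": "broad_spectrum_antibiotic",
      "bacterial infection": "broad_spectrum_antibiotic"
    }
  },
  "_shared_synonyms": {
    "insomnia": "sleep_disorder_insomnia",
    "sleep disorder": "sleep_disorder_insomnia",
    "sleep disorder/insomnia": "sleep_disorder_insomnia",
    "sleeplessness": "sleep_disorder_insomnia",
    "panic attack": "panic_attacks",
    "panic attacks": "panic_attacks",
    "headache": "headaches",
    "migraines": "migraine",
    "common cold": "common_cold",
    "restless legs syndrome": "restless_legs_syndrome",
    "irritable bowel syndrome": "irritable_bowel_syndrome",
    "mood control": "mood_control",
    "mood swings": "mood_control",
    "stress disorder": "stress_disorder"
  }
}
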