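# Default adverse-event term -> MedDRA system organ class map.
# Two tab-separated columns: term, SOC name. Terms are canonicalized on
# load (lower case, punctuation and whitespace collapsed). Exact-match
# lookup only; alias synonyms by adding rows sharing a SOC.
Pharyngitis	Infections and infestations
Nasopharyngitis	Infections and infestations
Upper respiratory tract infection	Infections and infestations
Urinary tract infection	Infections and infestations
Influenza	Infections and infestations
Bronchitis	Infections and infestations
Sinusitis	Infections and infestations
Pneumonia	Infections and infestations
Gastroenteritis	Infections and infestations
Otitis media	Infections and infestations
Cellulitis	Infections and infestations
Rhinitis	Infections and infestations
Sepsis	Infections and infestations
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Diarrhea	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Dyspepsia	Gastrointestinal disorders
Dry mouth	Gastrointestinal disorders
Flatulence	Gastrointestinal disorders
Gastritis	Gastrointestinal disorders
Fatigue	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Asthenia	General disorders and administration site conditions
Oedema peripheral	General disorders and administration site conditions
Chills	General disorders and administration site conditions
Injection site pain	General disorders and administration site conditions
Injection site erythema	General disorders and administration site conditions
Chest pain	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Death	General disorders and administration site conditions
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Somnolence	Nervous system disorders
Tremor	Nervous system disorders
Paraesthesia	Nervous system disorders
Syncope	Nervous system disorders
Migraine	Nervous system disorders
Seizure	Nervous system disorders
Neuropathy peripheral	Nervous system disorders
Heart failure	Cardiac disorders
Cardiac failure	Cardiac disorders
Myocardial infarction	Cardiac disorders
Atrial fibrillation	Cardiac disorders
Palpitations	Cardiac disorders
Tachycardia	Cardiac disorders
Bradycardia	Cardiac disorders
Angina pectoris	Cardiac disorders
Hypertension	Vascular disorders
Hypotension	Vascular disorders
Deep vein thrombosis	Vascular disorders
Flushing	Vascular disorders
Haematoma	Vascular disorders
Cough	Respiratory, thoracic and mediastinal disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Oropharyngeal pain	Respiratory, thoracic and mediastinal disorders
Epistaxis	Respiratory, thoracic and mediastinal disorders
Wheezing	Respiratory, thoracic and mediastinal disorders
Asthma	Respiratory, thoracic and mediastinal disorders
Pulmonary embolism	Respiratory, thoracic and mediastinal disorders
Back pain	Musculoskeletal and connective tissue disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Myalgia	Musculoskeletal and connective tissue disorders
Muscle spasms	Musculoskeletal and connective tissue disorders
Pain in extremity	Musculoskeletal and connective tissue disorders
Osteoarthritis	Musculoskeletal and connective tissue disorders
Neck pain	Musculoskeletal and connective tissue disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Alopecia	Skin and subcutaneous tissue disorders
Urticaria	Skin and subcutaneous tissue disorders
Dry skin	Skin and subcutaneous tissue disorders
Perioral dermatitis	Skin and subcutaneous tissue disorders
Erythema	Skin and subcutaneous tissue disorders
Hyperhidrosis	Skin and subcutaneous tissue disorders
Insomnia	Psychiatric disorders
Anxiety	Psychiatric disorders
Depression	Psychiatric disorders
Agitation	Psychiatric disorders
Confusional state	Psychiatric disorders
Irritability	Psychiatric disorders
Decreased appetite	Metabolism and nutrition disorders
Hyperglycaemia	Metabolism and nutrition disorders
Hypokalaemia	Metabolism and nutrition disorders
Dehydration	Metabolism and nutrition disorders
Hypoglycaemia	Metabolism and nutrition disorders
Weight decreased	Investigations
Weight increased	Investigations
Blood pressure increased	Investigations
Alanine aminotransferase increased	Investigations
Blood creatinine increased	Investigations
Anaemia	Blood and lymphatic system disorders
Neutropenia	Blood and lymphatic system disorders
Thrombocytopenia	Blood and lymphatic system disorders
Leukopenia	Blood and lymphatic system disorders
Lymphadenopathy	Blood and lymphatic system disorders
Febrile neutropenia	Blood and lymphatic system disorders
Renal failure	Renal and urinary disorders
Haematuria	Renal and urinary disorders
Urinary retention	Renal and urinary disorders
Proteinuria	Renal and urinary disorders
Dysuria	Renal and urinary disorders
Conjunctivitis	Eye disorders
Vision blurred	Eye disorders
Dry eye	Eye disorders
Cataract	Eye disorders
Vertigo	Ear and labyrinth disorders
Tinnitus	Ear and labyrinth disorders
Ear pain	Ear and labyrinth disorders
Deafness	Ear and labyrinth disorders
Hypersensitivity	Immune system disorders
Drug hypersensitivity	Immune system disorders
Anaphylactic reaction	Immune system disorders
Seasonal allergy	Immune system disorders
Hypothyroidism	Endocrine disorders
Hyperthyroidism	Endocrine disorders
Adrenal insufficiency	Endocrine disorders
Hepatotoxicity	Hepatobiliary disorders
Cholelithiasis	Hepatobiliary disorders
Jaundice	Hepatobiliary disorders
Hepatic failure	Hepatobiliary disorders
Erectile dysfunction	Reproductive system and breast disorders
Menorrhagia	Reproductive system and breast disorders
Breast pain	Reproductive system and breast disorders
Vaginal haemorrhage	Reproductive system and breast disorders
Spontaneous abortion	Pregnancy, puerperium and perinatal conditions
Premature delivery	Pregnancy, puerperium and perinatal conditions
Pre-eclampsia	Pregnancy, puerperium and perinatal conditions
Congenital anomaly	Congenital, familial and genetic disorders
Atrial septal defect	Congenital, familial and genetic disorders
Basal cell carcinoma	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
Breast cancer	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
Squamous cell carcinoma	Neoplasms benign, malignant and unspecified (incl cysts and polyps)
Fall	Injury, poisoning and procedural complications
Contusion	Injury, poisoning and procedural complications
Overdose	Injury, poisoning and procedural complications
Procedural pain	Injury, poisoning and procedural complications
Post procedural haemorrhage	Injury, poisoning and procedural complications
Hip arthroplasty	Surgical and medical procedures
Knee arthroplasty	Surgical and medical procedures
Hospitalisation	Surgical and medical procedures
Alcohol use	Social circumstances
Tobacco use	Social circumstances
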