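pt	soc
Abdominal discomfort	Gastrointestinal Disorders
Abdominal distension	Gastrointestinal Disorders
Abdominal pain	Gastrointestinal Disorders
Abdominal pain upper	Gastrointestinal Disorders
Alopecia	Skin And Subcutaneous Tissue Disorders
Anxiety	Psychiatric Disorders
Arthralgia	Musculoskeletal And Connective Tissue Disorders
Asthenia	General Disorders And Administration Site Conditions
Back pain	Musculoskeletal And Connective Tissue Disorders
Blood creatinine increased	Investigations
Blood gastrin increased	Investigations
Blood magnesium decreased	Investigations
Blood pressure decreased	Vascular Disorders
Bradycardia	Cardiac Disorders
Chest pain	General Disorders And Administration Site Conditions
Cholecystitis	Hepatobiliary Disorders
Colitis microscopic	Gastrointestinal Disorders
Constipation	Gastrointestinal Disorders
Cough	Respiratory, Thoracic And Mediastinal Disorders
Decreased appetite	Metabolism And Nutrition Disorders
Dementia	Nervous System Disorders
Depression	Psychiatric Disorders
Diarrhoea	Gastrointestinal Disorders
Dizziness	Nervous System Disorders
Dry mouth	Gastrointestinal Disorders
Dry throat	Respiratory, Thoracic And Mediastinal Disorders
Duodenal ulcer	Gastrointestinal Disorders
Dyspepsia	Gastrointestinal Disorders
Dysphagia	Gastrointestinal Disorders
Dyspnoea	Respiratory, Thoracic And Mediastinal Disorders
Eructation	Gastrointestinal Disorders
Facial paralysis	Nervous System Disorders
Fatigue	General Disorders And Administration Site Conditions
Feces discolored	Gastrointestinal Disorders
Flatulence	Gastrointestinal Disorders
Gastric cancer	Neoplasms Benign, Malignant And Unspecified (Incl Cysts And Polyps)
Gastric hemorrhage	Gastrointestinal Disorders
Gastric mucosal hypertrophy	Gastrointestinal Disorders
Gastric polyps	Gastrointestinal Disorders
Gastric ulcer	Gastrointestinal Disorders
Gastric ulcer hemorrhage	Gastrointestinal Disorders
Gastritis	Gastrointestinal Disorders
Gastrointestinal pain	Gastrointestinal Disorders
Gastrointestinal polyp hemorrhage	Gastrointestinal Disorders
Gastrooesophageal reflux disease	Gastrointestinal Disorders
Haematemesis	Gastrointestinal Disorders
Haematochezia	Gastrointestinal Disorders
Headache	Nervous System Disorders
Hepatic enzyme increased	Investigations
Hiatus hernia	Gastrointestinal Disorders
Hypergastrinaemia	Investigations
Hyperhidrosis	Skin And Subcutaneous Tissue Disorders
Hypertension	Vascular Disorders
Hypomagnesaemia	Metabolism And Nutrition Disorders
Illness	General Disorders And Administration Site Conditions
Insomnia	Psychiatric Disorders
Malabsorption	Gastrointestinal Disorders
Malaise	General Disorders And Administration Site Conditions
Migraine	Nervous System Disorders
Musculoskeletal discomfort	Musculoskeletal And Connective Tissue Disorders
Myalgia	Musculoskeletal And Connective Tissue Disorders
Nasopharyngitis	Infections And Infestations
Nausea	Gastrointestinal Disorders
Near death experience	Psychiatric Disorders
Neuroendocrine tumor	Neoplasms Benign, Malignant And Unspecified (Incl Cysts And Polyps)
Oedema peripheral	General Disorders And Administration Site Conditions
Oesophageal Candidiasis	Infections And Infestations
Oesophageal adenocarcinoma	Neoplasms Benign, Malignant And Unspecified (Incl Cysts And Polyps)
Oesophageal disorder	Gastrointestinal Disorders
Oesophageal pain	Gastrointestinal Disorders
Oesophagitis	Gastrointestinal Disorders
Oropharyngeal pain	Respiratory, Thoracic And Mediastinal Disorders
Palpitations	Cardiac Disorders
Paraesthesia oral	Nervous System Disorders
Polyp	General Disorders And Administration Site Conditions
Pruritus	Skin And Subcutaneous Tissue Disorders
Pyrexia	General Disorders And Administration Site Conditions
Rash	Skin And Subcutaneous Tissue Disorders
Renal impairment	Renal And Urinary Disorders
Sjogrens syndrome	Musculoskeletal And Connective Tissue Disorders
Somnolence	Nervous System Disorders
Stevens-Johnson Syndrome	Skin And Subcutaneous Tissue Disorders
Tachycardia	Cardiac Disorders
Thirst	General Disorders And Administration Site Conditions
Throat irritation	Respiratory, Thoracic And Mediastinal Disorders
Throat tightness	Respiratory, Thoracic And Mediastinal Disorders
Tremor	Nervous System Disorders
Urinary tract infection	Infections And Infestations
Urticaria	Skin And Subcutaneous Tissue Disorders
Varicose vein	Vascular Disorders
Vertigo	Nervous System Disorders
Vomiting	Gastrointestinal Disorders
Vomiting projectile	Gastrointestinal Disorders
Weight decreased	Investigations
Weight increased	Investigations
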