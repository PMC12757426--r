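pt
Nausea
Diarrhoea
Vomiting
Headache
Abdominal pain
Abdominal pain upper
Abdominal distension
Abdominal discomfort
Dyspepsia
Gastrooesophageal reflux disease
Constipation
Flatulence
Dizziness
Fatigue
Urticaria
Hypertension
Gastric polyps
Hypergastrinaemia
Blood gastrin increased
Gastritis
Rash
Pruritus
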