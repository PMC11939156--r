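patient_id,bmi,glycemia,cholesterol,triglycerides,nrpp
S001,38.07,161.23,197.86,257.68,16
S002,38.65,176.19,218.16,276.92,16
S003,30.99,131.77,245.57,140.85,6
S004,36.56,170.35,181.55,188.82,21
S005,34.39,173.79,198.2,197.98,12
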