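condition,system_chapter,is_mental
epilepsy,nervous,FALSE
cerebral palsy,nervous,FALSE
dementia,nervous,FALSE
parkinsonism,nervous,FALSE
migraine,nervous,FALSE
neuropathic pain,nervous,FALSE
chronic pain conditions,musculoskeletal,FALSE
chronic arthritis,musculoskeletal,FALSE
osteoporosis,musculoskeletal,FALSE
mental illness,mental,TRUE
insomnia,mental,TRUE
substance misuse,mental,TRUE
alcohol problems,mental,TRUE
reflux disorders,digestive,FALSE
chronic constipation,digestive,FALSE
inflammatory bowel disease,digestive,FALSE
dysphagia,digestive,FALSE
chronic liver disease,digestive,FALSE
diverticular disease,digestive,FALSE
peptic ulcer disease,digestive,FALSE
hypertension,circulatory,FALSE
coronary heart disease,circulatory,FALSE
cardiac arrhythmias,circulatory,FALSE
heart failure,circulatory,FALSE
stroke,circulatory,FALSE
peripheral vascular disease,circulatory,FALSE
chronic airway diseases,respiratory,FALSE
chronic pneumonia,respiratory,FALSE
bronchiectasis,respiratory,FALSE
diabetes,endocrine,FALSE
thyroid disorders,endocrine,FALSE
obesity,endocrine,FALSE
chronic kidney disease,genitourinary,FALSE
prostate disorders,genitourinary,FALSE
menopausal and perimenopausal,genitourinary,FALSE
anaemia,blood,FALSE
coagulopathy,blood,FALSE
hearing loss,ear,FALSE
visual impairment,eye,FALSE
cancer,neoplasms,FALSE
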