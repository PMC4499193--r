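# Feature -> panel routing table: maps a patient's most prominent primary
# clinical feature to exactly one of the 13 symptom-based panels.
cardiomyopathy: cardiovascular
congenital heart disease: cardiovascular
arrhythmias: cardiovascular
aneurysms: cardiovascular
hearing loss: deafness
dermatological features: dermatology
skeletal dysplasia: dysmorphology_dysplasia
dysmorphism: dysmorphology_dysplasia
pituitary and thyroid disorders: endocrinology
persistent jaundice: gastroenterology
aplastic anemia: hematology
metabolic disorders: iem
acidosis: iem
syndromic developmental delay: neurology
non-syndromic developmental delay: neurology
structural brain malformations: neurology
neurodegenerative disorders: neurology
movement disorders: neurology
peripheral neuropathy: neurology
myopathies: neurology
primary immunodeficiency: pid
chronic lung infection: pulmonology
suspected cystic fibrosis: pulmonology
glomerular disorders: renal
tubular disorders: renal
cystic kidney disease: renal
kidney malformation: renal
retinal dystrophy: vision
cataract: vision
aniridia: vision
microphthalmia: vision
corneal dystrophy: vision
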