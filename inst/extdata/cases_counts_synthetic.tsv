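panel_id	solved_by	missed_reason	n
cardiovascular	panel	none	67
cardiovascular	unsolved	none	176
deafness	panel	none	79
deafness	unsolved	none	68
dermatology	panel	none	42
dermatology	unsolved	none	26
dysmorphology_dysplasia	panel	none	134
dysmorphology_dysplasia	unsolved	none	220
endocrinology	panel	none	22
endocrinology	unsolved	none	14
gastroenterology	panel	none	21
gastroenterology	unsolved	none	52
hematology	panel	none	8
hematology	unsolved	none	25
iem	panel	none	72
iem	unsolved	none	50
neurology	panel	none	210
neurology	cnv	none	35
neurology	wes	design_flaw	14
neurology	wes	platform	6
neurology	unsolved	none	259
pid	panel	none	72
pid	unsolved	none	124
pulmonology	panel	none	13
pulmonology	unsolved	none	23
renal	panel	none	61
renal	unsolved	none	46
vision	panel	none	217
vision	unsolved	none	201
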