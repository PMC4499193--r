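variant_type	gene_in_panel	detected	n
snv	TRUE	TRUE	398
snv	TRUE	FALSE	30
indel	TRUE	TRUE	109
indel	TRUE	FALSE	43
snv	FALSE	FALSE	62
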