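variant_type	confirmed	n
snv	TRUE	819
snv	FALSE	62
indel	TRUE	154
indel	FALSE	43
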