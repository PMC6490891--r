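accession	domain
PF00005	NBD
PF01061	NBD
PF00664	TMD
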