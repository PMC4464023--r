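prot01	prot02
prot01	prot03
prot01	prot04
prot01	prot12
prot02	prot03
prot02	prot04
prot03	prot04
prot04	prot05
prot05	prot06
prot05	prot07
prot05	prot08
prot06	prot07
prot06	prot08
prot07	prot08
prot08	prot09
prot09	prot10
prot09	prot11
prot09	prot12
prot10	prot11
prot10	prot12
prot11	prot12
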