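predicted,ACRU,LIST,OTHER,PIEL,PIPA,PITA,QUGE,QULA,QUNI
ACRU,1,0,1,0,0,0,0,0,0
LIST,0,1,0,0,0,0,0,0,0
OTHER,1,1,0,0,0,0,1,0,0
PIEL,0,0,0,0,2,0,0,0,0
PIPA,0,0,0,1,82,0,0,1,0
PITA,0,0,0,0,4,1,1,0,0
QUGE,0,0,0,0,0,0,4,0,0
QULA,0,0,0,0,2,0,0,21,0
QUNI,0,0,0,0,0,0,0,0,1
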