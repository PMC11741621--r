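set_name,gene
SetA_synthetic,G01
SetA_synthetic,G02
SetA_synthetic,G03
SetB_synthetic,G03
SetB_synthetic,G04
SetB_synthetic,G05
SetB_synthetic,G06
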