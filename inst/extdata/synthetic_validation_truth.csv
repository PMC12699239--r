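"assay_id","planted_log2fc","direction"
"miR-181c-5p",2,"up"
"miR-182b-5p",2,"up"
"miR-196b-5p",2,"up"
"miR-145-5p",-2,"down"
"miR-199a-3p",-2,"down"
"miR-214-3p",-2,"down"
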