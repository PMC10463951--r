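"task","start","end","animal_id","correct_corner"
"FA",0,86400,"a1",1
"FA",0,86400,"a2",2
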