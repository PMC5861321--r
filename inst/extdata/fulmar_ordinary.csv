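"","pre-breeder","non-breeder","successful breeder","failed breeder"
"pre-breeder",0.90,0,0,0
"non-breeder",0,0.63,0.07,0.18
"successful breeder",0.01,0.18,0.67,0.49
"failed breeder",0.01,0.09,0.19,0.24
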