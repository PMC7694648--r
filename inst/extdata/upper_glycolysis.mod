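# upper_glycolysis
Glc, 6, source
FBP, 6, balanced
DHAP, 3, balanced
GAP, 3, balanced
LowerGlycolysis, 3, sink
f1: Glc (abcdef) -> FBP (abcdef)
f2: FBP (abcdef) -> DHAP (abc) + GAP (def)
f3: DHAP (abc) + GAP (def) -> FBP (abcdef)
f4: DHAP (abc) -> GAP (cba)
f5: GAP (abc) -> DHAP (cba)
f6: GAP (abc) -> LowerGlycolysis (abc)
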