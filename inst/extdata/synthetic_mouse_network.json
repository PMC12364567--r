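{
  "nodes": ["serum", "liver", "spleen", "kidney", "heart", "brain", "vastus muscle", "BAT", "WAT"],
  "edges": [
    ["BAT", "serum"],
    ["brain", "serum"],
    ["heart", "serum"],
    ["kidney", "serum"],
    ["liver", "serum"],
    ["serum", "spleen"],
    ["serum", "vastus muscle"],
    ["serum", "WAT"]
  ]
}
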