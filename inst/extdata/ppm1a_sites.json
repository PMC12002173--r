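{
  "comment": "Default PPM-family metal-coordination site model in PPM1A residue numbering, transcribed from the standard structural literature on the PPM1A binuclear active site. Edit or replace to use another reference numbering.",
  "reference_id": "PPM1A",
  "sites": [
    { "role": "M1", "position": 37,  "allowed": "E", "required": true },
    { "role": "M1", "position": 38,  "allowed": "D", "required": true },
    { "role": "M1", "position": 60,  "allowed": "D", "required": true },
    { "role": "M3", "position": 146, "allowed": "D", "required": false },
    { "role": "M2", "position": 239, "allowed": "D", "required": true },
    { "role": "M2", "position": 282, "allowed": "D", "required": true }
  ]
}
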