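{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Per-individual trait table",
  "description": "Row contract for the delimited-text trait tables read by read_trait_table(): one row per individual, wing and dentition morphometry in mm, dorsal and ventral CIELAB colour, molecular species label, hybrid flag and geographic zone.",
  "type": "object",
  "required": [
    "individual_id", "species", "is_hybrid", "zone",
    "FA", "D3_MC", "D3_F1", "D5_MC", "D5_F1", "C1_C1", "CM3",
    "L_dorsal", "a_dorsal", "b_dorsal", "L_ventral", "a_ventral", "b_ventral"
  ],
  "properties": {
    "individual_id": { "type": "string", "description": "Unique identifier" },
    "species": { "enum": ["isabellinus", "serotinus"], "description": "Molecular species label; for hybrids, the backcross parental assignment" },
    "is_hybrid": { "type": "boolean", "description": "Molecularly confirmed hybrid" },
    "zone": { "enum": ["allopatric", "sympatric"], "description": "Hybrids must be sympatric" },
    "FA": { "type": "number", "exclusiveMinimum": 0, "description": "Forearm length, mm" },
    "D3_MC": { "type": "number", "exclusiveMinimum": 0, "description": "Metacarpal of digit III, mm" },
    "D3_F1": { "type": "number", "exclusiveMinimum": 0, "description": "First phalanx of digit III, mm" },
    "D5_MC": { "type": "number", "exclusiveMinimum": 0, "description": "Metacarpal of digit V, mm" },
    "D5_F1": { "type": "number", "exclusiveMinimum": 0, "description": "First phalanx of digit V, mm" },
    "C1_C1": { "type": "number", "exclusiveMinimum": 0, "description": "Rostral width at the canines, mm" },
    "CM3": { "type": "number", "exclusiveMinimum": 0, "description": "Upper toothrow canine to third molar, mm" },
    "L_dorsal": { "type": "number", "minimum": 0, "maximum": 100 },
    "a_dorsal": { "type": "number" },
    "b_dorsal": { "type": "number" },
    "L_ventral": { "type": "number", "minimum": 0, "maximum": 100 },
    "a_ventral": { "type": "number" },
    "b_ventral": { "type": "number" }
  }
}
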