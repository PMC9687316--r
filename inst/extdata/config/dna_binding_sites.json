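{
  "comment": "DNA-binding residue ranges of the receptor's two high-confidence fragments (author numbering, inclusive). Overridable per run.",
  "sites": [
    {"fragment": "fragment1", "start": 210, "end": 276},
    {"fragment": "fragment2", "start": 312, "end": 370}
  ]
}
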