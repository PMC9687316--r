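{
  "comment": "Residue character used to classify interfacial contacts and NIS composition. Charged = D,E,K,R; remaining residues split polar/apolar following the contact-based affinity model the bundled weights come from (H kept with the polar set).",
  "classes": {
    "A": "apolar", "C": "apolar", "F": "apolar", "G": "apolar",
    "I": "apolar", "L": "apolar", "M": "apolar", "P": "apolar",
    "V": "apolar",
    "H": "polar", "N": "polar", "Q": "polar", "S": "polar",
    "T": "polar", "W": "polar", "Y": "polar",
    "D": "charged", "E": "charged", "K": "charged", "R": "charged"
  }
}
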