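{
  "version": "contact-ic-nis-1.0",
  "comment": "Published contact-based linear binding-affinity model: weighted interfacial-contact class-pair counts plus non-interacting-surface percentage terms. Terms: cc = charged-charged ICs, ca = charged-apolar ICs, pp = polar-polar ICs, pa = polar-apolar ICs, nis_apolar / nis_charged = percent composition of the non-interacting surface.",
  "weights": {
    "cc": -0.09459,
    "ca": -0.10007,
    "pp": 0.19577,
    "pa": -0.22671,
    "nis_apolar": 0.18681,
    "nis_charged": 0.1381
  },
  "intercept": -15.9433,
  "temperature": 298.15
}
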