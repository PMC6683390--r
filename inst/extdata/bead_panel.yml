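# Default bead panel for the glycoprotein-capture HPA/HLA antibody assay.
# Beads are listed in report/column order. The CD109 bead is shipped disabled:
# HPA-15 detection on this chemistry is unreliable (CD109 is low-abundance and
# degrades on storage); enable it explicitly if your assay validates it.
beads:
  - bead_id: GPIa/IIa
    code: LC10020-01
    target: GPIa/IIa
    systems: [HPA-5]
    role: hpa_capture
    enabled: true
  - bead_id: GPIba/IX
    code: LC10036-01
    target: GPIba/IX
    systems: [HPA-2]
    role: hpa_capture
    enabled: true
  - bead_id: HLA
    code: LC10050-01
    target: HLA-I
    systems: []
    role: hla_capture
    enabled: true
  - bead_id: GPIIb/IIIa
    code: LC10066-01
    target: GPIIb/IIIa
    systems: [HPA-1, HPA-3, HPA-4]
    role: hpa_capture
    enabled: true
  - bead_id: CD109
    code: LC10046-01
    target: CD109
    systems: [HPA-15]
    role: hpa_capture
    enabled: false
  - bead_id: IgG-control
    code: LC10086-01
    target: IgG-control
    systems: []
    role: positive_control
    enabled: true
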