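format: irisplex_params/1
reference: brown
provenance: >-
  EXTERNALLY SOURCED: coefficients of the published IrisPlex multinomial
  logistic model (trained on 3804 Dutch individuals; Liu et al. 2009,
  Curr Biol 19:R192-R193; Walsh et al. 2011, Forensic Sci Int Genet 5:170-180),
  transcribed by the package authors. The effect (minor) allele is counted at
  every marker. Verify against the original publications before operational
  casework use; package tests deliberately do not depend on this file.
panel:
- {rs_id: rs12913832, gene: HERC2, effect_allele: T, other_allele: C}
- {rs_id: rs1800407, gene: OCA2, effect_allele: A, other_allele: G}
- {rs_id: rs12896399, gene: SLC24A4, effect_allele: T, other_allele: G}
- {rs_id: rs16891982, gene: SLC45A2, effect_allele: C, other_allele: G}
- {rs_id: rs1393350, gene: TYR, effect_allele: A, other_allele: G}
- {rs_id: rs12203592, gene: IRF4, effect_allele: T, other_allele: C}
coefficients:
  blue:
    intercept: 3.94
    rs12913832: -4.81
    rs1800407: 1.40
    rs12896399: -0.58
    rs16891982: -1.30
    rs1393350: 0.47
    rs12203592: 0.70
  intermediate:
    intercept: 0.65
    rs12913832: -1.78
    rs1800407: 0.87
    rs12896399: -0.28
    rs16891982: -0.50
    rs1393350: 0.27
    rs12203592: 0.73
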