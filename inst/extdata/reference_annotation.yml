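elements:
- name: H1
  start_col: 36
  end_col: 56
- name: LA
  start_col: 57
  end_col: 74
- name: H2
  start_col: 75
  end_col: 95
- name: LB
  start_col: 96
  end_col: 139
- name: HB
  start_col: 128
  end_col: 139
- name: NPA1
  start_col: 128
  end_col: 130
- name: H3
  start_col: 140
  end_col: 160
- name: LC
  start_col: 161
  end_col: 178
- name: H4
  start_col: 179
  end_col: 196
- name: LD
  start_col: 197
  end_col: 204
- name: H5
  start_col: 205
  end_col: 225
- name: LE
  start_col: 226
  end_col: 263
- name: HE
  start_col: 232
  end_col: 244
- name: NPA2
  start_col: 232
  end_col: 234
- name: H6
  start_col: 264
  end_col: 284
arr_columns:
  H2: 89
  H5: 218
  LE1: 237
  LE2: 240
core_interval:
- 34
- 286
anchors:
- SoPIP2;1
- EcGlpF
subfamilies:
  AtPIP2;3: PIP
  SoPIP2;1: PIP
  PpPIP1;1: PIP
  PpPIP2;1: PIP
  PpGIP1;1: GIP
  EcGlpF: GIP
  AtTIP2;1: TIP
  OsTIP4;1: TIP
  OsNIP2;1: NIP
  AtNIP1;1: NIP
  ZmSIP2;1: SIP
  PpSIP1;1: SIP
  PpXIP1;1: XIP
  NtXIP1;1: XIP
  PpHIP1;1: HIP
  MIPA_REF1: MIPA
  MIPA_REF2: MIPA
  MIPB_REF1: MIPB
  MIPB_REF2: MIPB
  MIPC_REF1: MIPC
  MIPC_REF2: MIPC
  MIPD_REF1: MIPD
  MIPD_REF2: MIPD
  MIPE_REF1: MIPE
  MIPE_REF2: MIPE
  HsAQP5: AQP
  GLA_Llac: GLP
motifs:
- motif_id: kxsxxr
  kind: pattern
  pattern: K.S..R
  window_start: 118
  window_end: 129
  note: loop B phosphorylation motif of PIPs
- motif_id: pre_npa1
  kind: pattern
  pattern: GGH
  window_start: 110
  window_end: 118
  note: conserved motif leading up to NPA1; degenerate in MIPBs
- motif_id: gggan
  kind: pattern
  pattern: GGGAN
  window_start: 159
  window_end: 169
  note: loop C motif of PIPs
- motif_id: lxxn
  kind: pattern
  pattern: L..N
  window_start: 165
  window_end: 174
  note: loop C motif shared by MIPEs and classical mammalian aquaporins
- motif_id: dgcs
  kind: pattern
  pattern: DGCS
  window_start: 232
  window_end: 242
  note: loop E motif of MIPEs and algal PIPs; C sits at LE1
- motif_id: dxxxr
  kind: pattern
  pattern: D...R
  window_start: 235
  window_end: 242
  note: glycerol-channel motif just after NPA2
- motif_id: loopA_cys
  kind: pattern
  pattern: C
  window_start: 55
  window_end: 77
  note: loop A cysteine of plant PIPs (offset by two in algal PIPs)
- motif_id: h193
  kind: site
  anchor_id: SoPIP2;1
  resnums: '193'
  expect: H
  note: pH-gating histidine, loop D
- motif_id: ca_gating
  kind: site
  anchor_id: SoPIP2;1
  resnums: '28,31'
  expect: D,E
  note: N-terminal acidic residues of Ca2+ gating
- motif_id: s115
  kind: site
  anchor_id: SoPIP2;1
  resnums: '115'
  expect: S
  note: loop B phosphoserine
- motif_id: h2_gly
  kind: site
  anchor_id: SoPIP2;1
  resnums: '76'
  expect: G
  note: helix 2 packing glycine; missing in MIPCs
- motif_id: h3_gln
  kind: site
  anchor_id: SoPIP2;1
  resnums: '137'
  expect: Q
  note: helix 3 glutamine; S/T in MIPCs, E/N in GIPs
- motif_id: h6_pro
  kind: site
  anchor_id: SoPIP2;1
  resnums: '250'
  expect: P
  note: helix 6 proline; substituted in MIPCs and MIPDs
- motif_id: loopC_cys
  kind: site
  anchor_id: SoPIP2;1
  resnums: '166'
  expect: C
  note: loop C cysteine of MIPDs and XIPs
- motif_id: postHE_cys
  kind: site
  anchor_id: SoPIP2;1
  resnums: '240'
  expect: C
  note: cysteine in the loop after HE, conserved in MIPDs
- motif_id: glpf_packing
  kind: site
  anchor_id: EcGlpF
  resnums: '72,89,93'
  expect: T,F,Q
  note: GlpF-type core packing residues near NPA1 (EcGlpF numbering)
substrates:
- id: AtTIP2;1
  h2: H
  h5: I
  le1: G
  le2: R
  substrate: water
- id: GLA_Llac
  h2: 'Y'
  h5: V
  le1: P
  le2: R
  substrate: water/glycerol
- id: ZmSIP2;1
  h2: S
  h5: H
  le1: G
  le2: S
  substrate: unknown
- id: OsNIP2;1
  h2: G
  h5: S
  le1: G
  le2: R
  substrate: unknown
- id: OsTIP4;1
  h2: T
  h5: T
  le1: A
  le2: R
  substrate: water/glycerol
- id: HsAQP5
  h2: F
  h5: H
  le1: C
  le2: R
  substrate: water
- id: AtPIP2;3
  h2: F
  h5: H
  le1: T
  le2: R
  substrate: water
- id: PpGIP1;1
  h2: F
  h5: V
  le1: P
  le2: R
  substrate: glycerol
- id: CrMIPD1;1
  h2: 'N'
  h5: A
  le1: A
  le2: R
  substrate: glycerol
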