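# Curated domain architectures for the four complement proteins, HGVS Met-1
# numbering (signal peptide counted). Span authority: UniProt P08603 (CFH),
# P05156 (CFI), P15529 (MCP/CD46), P01024 (C3); boundaries curated from the
# literature on these proteins.
CFH:
  name: CFH
  gene: CFH
  uniprot: P08603
  length: 1231
  signal_peptide_end: 18
  domains:
    - {label: SCR-1,  class: SCR, span: 19-82}
    - {label: SCR-2,  class: SCR, span: 83-143}
    - {label: SCR-3,  class: SCR, span: 144-207}
    - {label: SCR-4,  class: SCR, span: 208-264}
    - {label: SCR-5,  class: SCR, span: 265-322}
    - {label: SCR-6,  class: SCR, span: 323-386}
    - {label: SCR-7,  class: SCR, span: 387-444}
    - {label: SCR-8,  class: SCR, span: 446-506}
    - {label: SCR-9,  class: SCR, span: 507-565}
    - {label: SCR-10, class: SCR, span: 566-625}
    - {label: SCR-11, class: SCR, span: 628-686}
    - {label: SCR-12, class: SCR, span: 689-746}
    - {label: SCR-13, class: SCR, span: 751-805}
    - {label: SCR-14, class: SCR, span: 809-866}
    - {label: SCR-15, class: SCR, span: 868-928}
    - {label: SCR-16, class: SCR, span: 929-986}
    - {label: SCR-17, class: SCR, span: 987-1045}
    - {label: SCR-18, class: SCR, span: 1046-1104}
    - {label: SCR-19, class: SCR, span: 1107-1165}
    - {label: SCR-20, class: SCR, span: 1167-1231}
CFI:
  name: CFI
  gene: CFI
  uniprot: P05156
  length: 583
  signal_peptide_end: 18
  domains:
    - {label: FIMAC,  class: FIMAC, span: 25-109}
    - {label: SRCR,   class: SRCR,  span: 113-220}
    - {label: LDLr-1, class: LDLr,  span: 226-262}
    - {label: LDLr-2, class: LDLr,  span: 263-301}
    - {label: SP,     class: SP,    span: 340-574}
MCP:
  name: MCP
  gene: CD46
  uniprot: P15529
  length: 392
  signal_peptide_end: 34
  domains:
    - {label: SCR-1, class: SCR, span: 35-96}
    - {label: SCR-2, class: SCR, span: 97-159}
    - {label: SCR-3, class: SCR, span: 160-225}
    - {label: SCR-4, class: SCR, span: 226-285}
    - {label: ST,    class: ST,  span: 286-326}
    - {label: TM,    class: TM,  span: 344-366}
    - {label: Cy,    class: Cy,  span: 367-392}
C3:
  name: C3
  gene: C3
  uniprot: P01024
  length: 1663
  signal_peptide_end: 22
  domains:
    - {label: MG1,   class: MG,    span: 23-128}
    - {label: MG2,   class: MG,    span: 129-231}
    - {label: MG3,   class: MG,    span: 232-338}
    - {label: MG4,   class: MG,    span: 339-443}
    - {label: MG5,   class: MG,    span: 444-545}
    - {label: MG6,   class: MG,    span: 546-577, parts: [749-806]}
    - {label: LNK,   class: LNK,   span: 578-667}
    - {label: ANA,   class: ANA,   span: 672-748}
    - {label: MG7,   class: MG,    span: 807-910}
    - {label: CUB,   class: CUB,   span: 911-962, parts: [1269-1330]}
    - {label: TED,   class: TED,   span: 963-1268}
    - {label: MG8,   class: MG,    span: 1331-1494}
    - {label: C345C, class: C345C, span: 1516-1663}
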