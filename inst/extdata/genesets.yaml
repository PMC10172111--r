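# Example gene-set annotation file: reference (control) genes probed for
# total RNA, cell-cycle marker panels, and a partial m6A label map.
reference_genes:
  - METTL3
  - METTL14
  - YTHDC2
  - YTHDF1
  - YTHDF2
  - YTHDF3
g1s_markers:
  - BCL2L1
  - CDC6
  - DSCC1
  - DTL
  - MCM5
  - UNG
  - SNN
  - FEN1
  - GINS2
  - GMNN
  - MCM2
  - MCM4
  - MCM6
  - PCNA
  - PRIM1
  - RRM1
  - TYMS
  - UHRF1
  - CDCA7
g2m_markers:
  - TOP2A
  - TPX2
  - UBE2C
  - HJURP
  - BIRC5
  - CCNB2
  - CDCA2
  - CKAP5
  - CKS1B
  - CKS2
  - HMGB2
  - NCAPD2
  - NDC80
  - NUF2
  - TACC3
  - TMPO
  - MKI67
  - CENPF
m6a_labels:
  MCM5: m6a
  PCNA: non_m6a
  TOP2A: unknown
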