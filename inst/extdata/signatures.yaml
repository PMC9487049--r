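# Editable signature-set configuration for immune-panel scoring.
# Gene lists are compact placeholders built from widely used marker genes for
# each population/pathway; the proprietary panel weights and full membership
# lists of commercial analysis software are not reproduced. Treat this file
# as configuration and substitute project-specific lists as needed.
CD45:
  kind: cell_type
  genes: [PTPRC]
T cells:
  kind: cell_type
  genes: [CD3D, CD3E, CD3G, CD6, SH2D1A, TRAT1]
CD8 T cells:
  kind: cell_type
  genes: [CD8A, CD8B]
Cytotoxic cells:
  kind: cell_type
  genes: [GZMA, GZMB, GZMH, GZMK, PRF1, GNLY, KLRK1, KLRC1, NKG7]
Exhausted CD8:
  kind: cell_type
  genes: [LAG3, PDCD1, HAVCR2, CTLA4, EOMES]
Treg:
  kind: cell_type
  genes: [FOXP3, IL2RA, IKZF2]
B cells:
  kind: cell_type
  genes: [CD19, MS4A1, CD79A, CD79B, BLK]
NK cells:
  kind: cell_type
  genes: [NCR1, KIR2DL3, KIR3DL1, XCL1, XCL2]
Macrophages:
  kind: cell_type
  genes: [CD68, CD163, MARCO, MSR1, MRC1]
Neutrophils:
  kind: cell_type
  genes: [FPR1, S100A12, CEACAM3, FCGR3B, CSF3R]
Mast cells:
  kind: cell_type
  genes: [TPSAB1, TPSB2, CPA3, MS4A2]
DC:
  kind: cell_type
  genes: [CCL13, CD209, HSD11B1]
Th1 cells:
  kind: cell_type
  genes: [TBX21, IL12RB2, IFNG]
TILs:
  kind: cell_type
  genes: [PTPRC, CD3E, CD4, CD8A, CD19, NCR1]
M1 macrophages:
  kind: cell_type
  genes: [NOS2, IL12B, CXCL9, CXCL10, TNF]
M2 macrophages:
  kind: cell_type
  genes: [CD163, MRC1, CCL22, IL10, TGFB1]
Cytotoxicity:
  kind: pathway
  genes: [GZMA, GZMB, PRF1, GNLY, KLRB1, KLRD1]
Antigen processing:
  kind: pathway
  genes: [HLA-A, HLA-B, HLA-C, TAP1, TAP2, B2M, PSMB9]
IFN-gamma signalling:
  kind: pathway
  genes: [IFNG, IFNGR1, STAT1, IRF1, CXCL9, CXCL10, IDO1]
Complement:
  kind: pathway
  genes: [C1QA, C1QB, C2, C3, C8G, CFB]
T cell functions:
  kind: pathway
  genes: [CD28, ICOS, CD40LG, IL2, IL12RB2, ZAP70]
Macrophage functions:
  kind: pathway
  genes: [CD68, MSR1, MARCO, MST1R, TLR2, TLR4]
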