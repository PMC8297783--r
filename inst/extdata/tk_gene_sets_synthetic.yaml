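# TK gene-set catalog for the MIBC co-alteration pipeline.
#
# group1_TK (31, high in BS/N) and group2_TK (21, high in LP) are the
# published panel memberships; ctRTK (19 cabozantinib-target RTKs), the
# EMT transcriptional activators (9) and the RTK -> cognate-ligand map are
# likewise as published. group3_TK (phenotype-independent TKs, 37) is only
# partially public: the 10 RTKs known to belong to it are listed first and
# the set is completed to its stated size with representative human TK
# symbols — group3_TK membership beyond those 10 is SYNTHETIC and only the
# set size should be relied on.
sets:
  group1_TK: [ABL1, ABL2, AXL, BTK, CSF1R, DDR2, EPHA3, EPHB2, EPHB3, EPHB4,
              FER, FGFR1, FLT3, FYN, HCK, IGF1R, ITK, JAK1, JAK2, JAK3, LCK,
              LYN, MET, PDGFRA, PDGFRB, PTK7, ROR1, ROR2, TEK, TIE1, ZAP70]
  group2_TK: [DDR1, EPHA1, EPHB6, ERBB2, ERBB3, ERBB4, FGFR2, FGFR3, INSR,
              LMTK2, MERTK, MST1R, PTK2, PTK6, SRC, SRMS, STYK1, TNK1, TNK2,
              TXK, TYK2]
  group3_TK: [FLT1, FLT4, KDR, KIT, NTRK1, NTRK2, NTRK3, RET, ROS1, TYRO3,
              EGFR, ALK, LTK, MUSK, RYK, AATK, BLK, BMX, CSK, MATK, FES, FGR,
              FRK, YES1, TEC, SYK, PTK2B, EPHA2, EPHA4, EPHA5, EPHA6, EPHA7,
              EPHA8, EPHA10, EPHB1, INSRR, FGFR4]
  ctRTK: [AXL, CSF1R, DDR1, DDR2, FLT1, FLT3, FLT4, KDR, KIT, MET, MERTK,
          MST1R, NTRK1, NTRK2, NTRK3, RET, ROS1, TEK, TYRO3]
  EMT_TA: [MYC, RUNX2, SNAI1, SNAI2, SOX2, SOX9, TWIST1, ZEB1, ZEB2]
pair_maps:
  rtk_ligand:
    AXL: [GAS6]
    CSF1R: [CSF1]
    DDR2: [COL1A1, COL3A1, COL4A1, COL5A1, COL10A1]
    KDR: [VEGFA]
    MST1R: [MST1]
    PDGFRA: [PDGFA]
    TEK: [ANGPT2]
    NTRK2: [NTF4]
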