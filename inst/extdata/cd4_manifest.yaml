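# Role manifest for the bundled CD4+ T-cell network (synthetic reconstruction).
# Maps scenario roles to node identifiers so the engine stays rule-set-agnostic.
network: cd4_tcell_synthetic
theta: 0.5
lineages:
  Th1:  {tf: TBET,  cytokines: [IFNG]}
  Th2:  {tf: GATA3, cytokines: [IL4]}
  Th17: {tf: RORGT, cytokines: [IL17, IL21]}
  Treg: {tf: FOXP3, cytokines: [TGFB, IL10]}
  TFH:  {tf: BCL6,  cytokines: [IL9, IL21, CD40L]}
inputs:
  cytokines: [IFNG_e, IL12_e, IL18_e, IL33_e, IL4_e, TGFB_e, IL10_e, IL21_e, IL6_e]
  th1_group: [IL12_e, IFNG_e, IL18_e, IL33_e]
  nutrients: {glutamine: GLN, tryptophan: TRP, glucose: GLC, fatty_acids: FA}
  hypoxia: HYP
  stimulation: [MHC, CD8086]
ctla4: CTLA4
metabolic:
  glycolysis: GLYC
  oxphos: OXPHOS
activation_core:
  sustained: [NFAT, NFKB, AP1, IL2, CD25]
  transient_band: [LCK, ZAP70, LAT, PLCG, SOS]
initial:
  # naive cell: low oxidative phosphorylation, active AMPK
  AMPK: 0.5
  OXPHOS: 0.2
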