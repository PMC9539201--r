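# Bundled 68-node model of early CD4+ T-cell activation and differentiation.
# SYNTHETIC RECONSTRUCTION: the rule set was curated from the published
# description of the network topology and behaviour, not transcribed from a
# machine-readable source; rule-level fidelity to any specific published
# rule listing is not guaranteed. Numeric literals inside rules encode
# partial (weighted) regulatory influences under the multiplicative norm.
NETWORK cd4_tcell_synthetic VERSION 1.0-synthetic
INPUT MHC MODULE stimulation-input
INPUT CD8086 MODULE stimulation-input
INPUT IFNG_e MODULE cytokine-input
INPUT IL12_e MODULE cytokine-input
INPUT IL18_e MODULE cytokine-input
INPUT IL33_e MODULE cytokine-input
INPUT IL4_e MODULE cytokine-input
INPUT TGFB_e MODULE cytokine-input
INPUT IL10_e MODULE cytokine-input
INPUT IL21_e MODULE cytokine-input
INPUT IL6_e MODULE cytokine-input
INPUT GLN MODULE nutrient-oxygen-input
INPUT TRP MODULE nutrient-oxygen-input
INPUT GLC MODULE nutrient-oxygen-input
INPUT FA MODULE nutrient-oxygen-input
INPUT HYP MODULE nutrient-oxygen-input
NODE TCR MODULE activation-core ALPHA 1 RULE MHC
NODE CD28 MODULE activation-core ALPHA 1 RULE CD8086 & !CTLA4dim
NODE LCK MODULE activation-core ALPHA 1 RULE TCR
NODE ZAP70 MODULE activation-core ALPHA 1 RULE LCK
NODE LAT MODULE activation-core ALPHA 1 RULE ZAP70
NODE PLCG MODULE activation-core ALPHA 1 RULE LAT
NODE SOS MODULE activation-core ALPHA 1 RULE LAT
NODE RAS MODULE activation-core ALPHA 1 RULE SOS | JAK3
NODE ERK MODULE activation-core ALPHA 1 RULE RAS
NODE CA MODULE activation-core ALPHA 1 RULE PLCG | JAK3
NODE NFAT MODULE activation-core ALPHA 1 RULE CA
NODE PKCTH MODULE activation-core ALPHA 1 RULE PLCG & CD28 | JAK3
NODE NFKB MODULE activation-core ALPHA 1 RULE PKCTH
NODE AP1 MODULE activation-core ALPHA 1 RULE ERK & PKCTH
NODE IL2 MODULE activation-core ALPHA 1 RULE NFAT & AP1 & NFKB & !CTLA4dim & !NDRG1
NODE CD25 MODULE activation-core ALPHA 1 RULE NFKB | STAT5
NODE JAK3 MODULE activation-core ALPHA 1 RULE IL2 & CD25
NODE STAT5 MODULE activation-core ALPHA 1 RULE JAK3
NODE CTLA4 MODULE regulatory ALPHA 1 RULE FOXP3 | TCR & NFAT
NODE CTLA4dim MODULE regulatory ALPHA 1 RULE CTLA4 & 0.4
NODE NDRG1 MODULE regulatory ALPHA 1 RULE NFAT & !AP1
NODE PI3K MODULE metabolic ALPHA 1 RULE CD28 | JAK3
NODE MTORC2 MODULE metabolic ALPHA 1 RULE AMPK
NODE AKT MODULE metabolic ALPHA 1 RULE PI3K
NODE MTOR MODULE metabolic ALPHA 1 RULE AKT
NODE MTORC1 MODULE metabolic ALPHA 1 RULE (MTOR | AKG) & !MTORC2 & !FOXP3
NODE AMPK MODULE metabolic ALPHA 1 RULE MTORC1 & !GLYC & !GLYC & IL6_e & IL6_e | FOXP3 | AMPK & !MTOR
NODE AKG MODULE metabolic ALPHA 1 RULE GLN
NODE GLUT1 MODULE metabolic ALPHA 1 RULE GLC & (AKT | HIF1A)
NODE GLYC MODULE metabolic ALPHA 1 RULE GLUT1 & (MTORC1 | HIF1A) & !BCL6 & 0.52
NODE OXPHOS MODULE metabolic ALPHA 1 RULE AMPK & (FA | AKG) & !GLYC
NODE HIF1A MODULE metabolic ALPHA 1 RULE HYP & (AKT | MTORC1)
NODE STAT1 MODULE lineage-TF ALPHA 1 RULE IFNG_e & (IFNG_e | HIF1A) | IFNG
NODE STAT4 MODULE lineage-TF ALPHA 1 RULE IL12_e & IL18_e & IL33_e
NODE STAT6 MODULE lineage-TF ALPHA 1 RULE IL4_e | IL4
NODE STAT3 MODULE lineage-TF ALPHA 1 RULE IL6_e | IL21_e
NODE TBET MODULE lineage-TF ALPHA 1 RULE AP1 & STAT1 & STAT4 & (AKG | TBET & 0.6) & (TRP | 0.2) & !(GATA3 & 0.8) & !(FOXP3 & 0.9)
NODE GATA3 MODULE lineage-TF ALPHA 1 RULE AP1 & STAT6 & STAT6 & (STAT5 | STAT6 & 0.75) & !(TBET & 0.75) & !(BCL6 & 0.8) & !(RORGT & 0.5)
NODE RORGT MODULE lineage-TF ALPHA 1 RULE AP1 & (TGFBS & (STAT3 | HIF1A) & (IL6_e | HIF1A | !IL10S) | IL10S & STAT3 & TRP & (IL6_e | HIF1A | !TBET) & 0.8) & !(TBET & 0.15) & !(FOXP3 & 0.5) & !(IL4_e & IL4_e & (GATA3 | IFNG) & 0.8) & !(BCL6 & 0.5)
NODE FOXP3 MODULE lineage-TF ALPHA 1 RULE AP1 & TGFBS & TGFBS & (STAT5 | TGFBS & IL10S & 0.75) & !HIF1A & !TBET & !(RORGT & 0.6) & !(IL6_e & IL21_e)
NODE BCL6 MODULE lineage-TF ALPHA 1 RULE AP1 & MTORC1 & STAT3 & (IL6_e | IL21_e) & !(TGFBS & 0.8) & !(RORGT & 0.8) & !(TBET & 0.8) & !(GATA3 & 0.8)
NODE IFNG MODULE output-cytokine ALPHA 1 RULE TBET
NODE IL4 MODULE output-cytokine ALPHA 1 RULE GATA3
NODE IL17 MODULE output-cytokine ALPHA 1 RULE RORGT
NODE IL21 MODULE output-cytokine ALPHA 1 RULE RORGT & STAT3 | BCL6
NODE IL9 MODULE output-cytokine ALPHA 1 RULE BCL6
NODE IL10 MODULE output-cytokine ALPHA 1 RULE FOXP3
NODE TGFB MODULE output-cytokine ALPHA 1 RULE FOXP3
NODE CD40L MODULE output-cytokine ALPHA 1 RULE BCL6
NODE CXCR5 MODULE output-cytokine ALPHA 1 RULE BCL6
NODE TGFBS MODULE lineage-TF ALPHA 1 RULE TGFB_e | TGFB & 0.5
NODE IL10S MODULE lineage-TF ALPHA 1 RULE IL10_e | IL10 & 0.5
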