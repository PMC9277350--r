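cell_line	tissue
NPC	amygdala
NPC	anterior_cingulate_cortex
NPC	caudate
NPC	cerebellar_hemisphere
NPC	cerebellum
NPC	cortex
NPC	frontal_cortex
NPC	hippocampus
NPC	hypothalamus
NPC	nucleus_accumbens
NPC	putamen
NPC	spinal_cord
NPC	substantia_nigra
SKL	muscle_skeletal
HA1E	kidney_cortex
ASC	adipose_subcutaneous
ASC	adipose_visceral
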