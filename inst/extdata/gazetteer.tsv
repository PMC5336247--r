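protein	hemoglobin
protein	albumin
protein	cytochrome p450
protein	glutathione
protein	insulin
protein	transferrin
DNA	dna adduct
DNA	dna
RNA	messenger rna
RNA	mrna
cell_line	hepg2
cell_line	mcf-7
cell_type	lymphocyte
cell_type	lymphocytes
cell_type	erythrocyte
cell_type	erythrocytes
cell_type	hepatocyte
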