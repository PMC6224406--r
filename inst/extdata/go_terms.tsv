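term	hallmark
cell adhesion	invasion and metastasis
inflammatory response	tumor-promoting inflammation
NIK/NF-kB signaling	proliferative signaling
MAPK signaling	proliferative signaling
regulation of B-cell activation	immune evasion
B-cell differentiation	immune evasion
B-cell proliferation	proliferative signaling
cytokine signaling	tumor-promoting inflammation
apoptotic process	resisting cell death
regulation of apoptotic signaling	resisting cell death
DNA damage response	genome instability
DNA repair	genome instability
cell cycle checkpoint	evading growth suppressors
negative regulation of cell cycle	evading growth suppressors
G protein-coupled receptor signaling	proliferative signaling
transcriptional regulation	proliferative signaling
post-translational protein modification	proliferative signaling
hematopoietic development	immune evasion
angiogenesis	inducing angiogenesis
telomere maintenance	replicative immortality
glycolytic process	deregulating cellular energetics
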