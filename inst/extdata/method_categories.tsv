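mi_code	category
MI:0018	Two Hybrid (2Hyb)
MI:0397	Two Hybrid (2Hyb)
MI:0398	Two Hybrid (2Hyb)
MI:0399	Two Hybrid (2Hyb)
MI:1112	Two Hybrid (2Hyb)
MI:0004	Affinity Purification (AP)
MI:0006	Affinity Purification (AP)
MI:0007	Affinity Purification (AP)
MI:0019	Affinity Purification (AP)
MI:0096	Affinity Purification (AP)
MI:0676	Affinity Purification (AP)
MI:0090	Complementation (PCA)
MI:0111	Complementation (PCA)
MI:0112	Complementation (PCA)
MI:0012	Resonance Energy Transfer (RET)
MI:0055	Resonance Energy Transfer (RET)
MI:0416	Imaging (Img)
MI:0428	Imaging (Img)
MI:0663	Imaging (Img)
MI:0114	Structure (Struct)
MI:0826	Structure (Struct)
MI:0013	Biophysical (Biophys)
MI:0065	Biophysical (Biophys)
MI:0107	Biophysical (Biophys)
MI:0030	Cross-linking (XL)
MI:0031	Cross-linking (XL)
MI:0415	Enzymatic Assay (Enz)
MI:0424	Enzymatic Assay (Enz)
MI:0008	Protein Array (Array)
MI:0089	Protein Array (Array)
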