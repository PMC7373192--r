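OTU	Size	Taxonomy
Otu0001	2000	Bacteria(100);Proteobacteria(100);Gammaproteobacteria(100);Pseudomonadales(100);Pseudomonadaceae(100);Pseudomonas(100);
Otu0002	175	Bacteria(100);Bacteroidetes(97);Bacteroidia(97);Bacteroidales(97);Prevotellaceae(95);Prevotella(95);
Otu0003	90	Bacteria(100);Firmicutes(99);Negativicutes(99);Veillonellales(99);Veillonellaceae(99);Veillonella(98);
Otu0004	1930	Bacteria(100);Actinobacteria(100);Actinobacteria(100);Micrococcales(100);Micrococcaceae(100);Rothia(100);
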