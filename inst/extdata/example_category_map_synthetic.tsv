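# SYNTHETIC example term-to-category mapping, for demonstration only.
# Term-to-category assignment is a manual curation step; this file shows
# the expected two-column format with illustrative GO/KEGG-style term ids
# grouped under coarse functional category names. It is NOT an
# authoritative annotation and must not be used for real analyses.
term	category
GO:0032635	Cytokine production and response
GO:0032640	Cytokine production and response
GO:0032612	Cytokine production and response
GO:0032609	Cytokine production and response
GO:0032615	Cytokine production and response
GO:0002218	Immune system response
GO:0002250	Immune system response
GO:0002253	Immune system response
GO:0002376	Immune system response
GO:0042116	Immune system response
GO:0045859	Signaling pathway
GO:0043408	Signaling pathway
GO:0007265	Signaling pathway
GO:0038093	Signaling pathway
GO:0051056	Signaling pathway
hsa04630	Signaling pathway
GO:0007049	Cell-cycle regulation and progression
GO:0051301	Cell-cycle regulation and progression
GO:0000278	Cell-cycle regulation and progression
hsa04110	Cell-cycle regulation and progression
GO:0006310	DNA recombination/metabolic process
GO:0006259	DNA recombination/metabolic process
GO:0006281	DNA repair and response to stress
GO:0006974	DNA repair and response to stress
GO:0000793	Chromosome (condensed)
GO:0000775	Chromosome (condensed)
GO:0006909	Phagocytosis and endocytosis
GO:0006897	Phagocytosis and endocytosis
GO:0030595	Cell migration and chemotaxis
GO:0016477	Cell migration and chemotaxis
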