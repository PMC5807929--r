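# Bundled restriction-enzyme panel for the Pocillopora mtORF/PocHistone
# RFLP assays. REBASE-style semantics: cut_top = recognition bases 5' of
# the top-strand cut for a forward match; cut_bottom = same on the
# bottom strand read 5'->3'.
name	recognition	cut_top	cut_bottom
SacI	GAGCTC	5	1
XhoI	CTCGAG	1	5
AciI	CCGC	1	3
AlwNI	CAGNNNCTG	6	3
NlaIV	GGNNCC	3	3
Tsp45I	GTSAC	0	5
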