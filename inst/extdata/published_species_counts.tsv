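# Published per-species transcription factor (TF) and membrane-bound TF (MTF)
# locus counts for the 14 plant proteomes of the reference genome-wide survey.
# Columns: species code, species name, lineage, TF loci, MTF loci.
species	name	lineage	tf_loci	mtf_loci
Cr	Chlamydomonas reinhardtii	Chlorophyta	230	37
Pp	Physcomitrella patens	Bryophyta	1079	49
Pa	Picea abies	Gymnosperm	1851	71
Bd	Brachypodium distachyon	Monocot	1557	50
Os	Oryza sativa	Monocot	1859	85
Sb	Sorghum bicolor	Monocot	1826	62
Zm	Zea mays	Monocot	2231	110
Gm	Glycine max	Eudicot	3714	117
Mt	Medicago truncatula	Eudicot	1577	71
Gr	Gossypium raimondii	Eudicot	2634	111
Sl	Solanum lycopersicum	Eudicot	1845	58
Pt	Populus trichocarpa	Eudicot	2455	89
At	Arabidopsis thaliana	Eudicot	1716	64
Vv	Vitis vinifera	Eudicot	1276	115
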