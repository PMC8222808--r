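# Macrophage polarization transcriptional regulatory network, tumor
# microenvironment variant -- SYNTHETIC RECONSTRUCTION.
#
# This file is NOT the authors' published supplementary rule file (which is
# distributed as Supplementary Material SM1 alongside the source article and
# could not be obtained in this build environment). It was transcribed from
# the article's narrative description of the signaling cascades and from the
# behaviors reported in its figures, and it reproduces the printed structural
# facts: 29 nodes and 60 distinct regulator->target interactions (self-loops
# counted), every node with at least two interactions (the published network
# is the already-reduced one). Extracellular signals persist through a
# self-loop (constitutive receptor assumption); secreted cytokines follow
# the transcription factors that drive their secretion.
#
# Attractor counts computed from this reconstruction are NOT expected to
# match the article's printed counts.
targets, factors
HMGB1, HMGB1
IFNB, IFNB
IL4, IL4
IL13, IL13
IL1B, IL1B
IGG, IGG
GCGCR, GCGCR
A2A, A2A
HYPOXIA, HYPOXIA
MCSF, MCSF
TLR4, HMGB1 | FRA1 | TLR4
FCR, IGG
ERK, FCR
AP1, IL1B | AP1
FRA1, FRA1
NFKB, (TLR4 | MCSF | TNFA) & !(KLF4 | STAT3 | A2A | IL10)
STAT1, (IFNG | IFNB | STAT1) & !SOCS1
STAT3, (IL10 | (MCSF & IL6) | ((TGFB | A2A) & GCGCR)) & !STAT1
STAT6, (IL4 | IL13) & !STAT1
SOCS1, STAT6
KLF4, STAT6
HIF1A, HYPOXIA | IL6 | TGFB | A2A
IFNG, STAT1 & !SOCS1
TNFA, NFKB & !GCGCR
TGFB, TGFB | STAT3 | STAT6
IL10, STAT3 | STAT6
IL6, IL6 | ERK
IL12, NFKB | STAT1
VEGF, HIF1A | STAT3
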