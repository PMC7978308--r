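# DNA-damage-repair gene -> pathway map: TP53 plus eight functional
# families (47 genes total). SYNTHETIC / NON-CANONICAL reconstruction: the
# curated 47-gene study list is not public, so beyond the genes named in
# the literature (TP53, ATM, BRCA1/2, PRKDC, ATR, POLE, POLD1, DDR2,
# MUTYH, the MSH/MLH mismatch-repair family) this map is filled with
# standard members of each repair pathway. Edit freely; load_ddr_map()
# warns if the total is not 47.
TP53: TP53
# checkpoint factors (CPF)
ATM: checkpoint_factors
ATR: checkpoint_factors
CHEK1: checkpoint_factors
CHEK2: checkpoint_factors
ATRX: checkpoint_factors
# Fanconi anemia (FA)
FANCA: fanconi_anemia
FANCC: fanconi_anemia
FANCD2: fanconi_anemia
FANCE: fanconi_anemia
FANCF: fanconi_anemia
FANCG: fanconi_anemia
FANCI: fanconi_anemia
FANCL: fanconi_anemia
FANCM: fanconi_anemia
PALB2: fanconi_anemia
# mismatch repair (MMR)
MLH1: mismatch_repair
MLH3: mismatch_repair
MSH2: mismatch_repair
MSH3: mismatch_repair
MSH6: mismatch_repair
PMS1: mismatch_repair
PMS2: mismatch_repair
# homologous recombination (HR)
BRCA1: homologous_recombination
BRCA2: homologous_recombination
RAD50: homologous_recombination
RAD51: homologous_recombination
RAD51C: homologous_recombination
RAD51D: homologous_recombination
MRE11A: homologous_recombination
NBN: homologous_recombination
# nucleotide excision repair (NER)
ERCC1: nucleotide_excision_repair
ERCC2: nucleotide_excision_repair
ERCC3: nucleotide_excision_repair
ERCC4: nucleotide_excision_repair
ERCC5: nucleotide_excision_repair
XPA: nucleotide_excision_repair
XPC: nucleotide_excision_repair
# base excision repair (BER)
MUTYH: base_excision_repair
OGG1: base_excision_repair
PARP1: base_excision_repair
XRCC1: base_excision_repair
# non-homologous end joining (NHEJ)
PRKDC: non_homologous_end_joining
LIG4: non_homologous_end_joining
# other replication-fidelity / repair-associated genes
POLE: other
POLD1: other
DDR2: other
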