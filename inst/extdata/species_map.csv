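species_code,jenkins_group,chojnacky_group,wood_specific_gravity
PSME,douglas_fir,pseudotsuga,0.45
SESE3,cedar_larch,cupressaceae_high_sg,0.36
PIPO,pine,pinus_low_sg,0.38
PISA2,pine,pinus_low_sg,0.42
ABCO,true_fir_hemlock,abies_high_sg,0.37
TSHE,true_fir_hemlock,tsuga,0.42
QUAG,hard_maple_oak_hickory_beech,quercus_evergreen,0.66
QUKE,hard_maple_oak_hickory_beech,quercus_deciduous,0.51
QUGA4,hard_maple_oak_hickory_beech,quercus_deciduous,0.58
LIDE3,mixed_hardwood,fagaceae_evergreen,0.52
UMCA,mixed_hardwood,lauraceae,0.51
ARME,mixed_hardwood,ericaceae,0.58
ACMA3,soft_maple_birch,acer,0.44
ALRU2,aspen_alder,alnus,0.37
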