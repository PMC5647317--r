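family,group_id,parameter,value
jenkins,cedar_larch,b0,-2.0336
jenkins,cedar_larch,b1,2.2592
jenkins,cedar_larch,dbh_max_sampled,250
jenkins,douglas_fir,b0,-2.2304
jenkins,douglas_fir,b1,2.4435
jenkins,douglas_fir,dbh_max_sampled,210
jenkins,true_fir_hemlock,b0,-2.5384
jenkins,true_fir_hemlock,b1,2.4814
jenkins,true_fir_hemlock,dbh_max_sampled,230
jenkins,pine,b0,-2.5356
jenkins,pine,b1,2.4349
jenkins,pine,dbh_max_sampled,180
jenkins,spruce,b0,-2.0773
jenkins,spruce,b1,2.3323
jenkins,spruce,dbh_max_sampled,100
jenkins,aspen_alder,b0,-2.2094
jenkins,aspen_alder,b1,2.3867
jenkins,aspen_alder,dbh_max_sampled,70
jenkins,soft_maple_birch,b0,-1.9123
jenkins,soft_maple_birch,b1,2.3651
jenkins,soft_maple_birch,dbh_max_sampled,66
jenkins,mixed_hardwood,b0,-2.48
jenkins,mixed_hardwood,b1,2.4835
jenkins,mixed_hardwood,dbh_max_sampled,56
jenkins,hard_maple_oak_hickory_beech,b0,-2.0127
jenkins,hard_maple_oak_hickory_beech,b1,2.4342
jenkins,hard_maple_oak_hickory_beech,dbh_max_sampled,73
jenkins,woodland,b0,-0.7152
jenkins,woodland,b1,1.7029
jenkins,woodland,dbh_max_sampled,78
chojnacky,pseudotsuga,b0,-2.4623
chojnacky,pseudotsuga,b1,2.4852
chojnacky,pseudotsuga,dbh_max_sampled,210
chojnacky,cupressaceae_high_sg,b0,-2.1652
chojnacky,cupressaceae_high_sg,b1,2.3263
chojnacky,cupressaceae_high_sg,dbh_max_sampled,250
chojnacky,pinus_low_sg,b0,-2.6177
chojnacky,pinus_low_sg,b1,2.4638
chojnacky,pinus_low_sg,dbh_max_sampled,180
chojnacky,abies_high_sg,b0,-2.3123
chojnacky,abies_high_sg,b1,2.3482
chojnacky,abies_high_sg,dbh_max_sampled,230
chojnacky,tsuga,b0,-2.348
chojnacky,tsuga,b1,2.3876
chojnacky,tsuga,dbh_max_sampled,190
chojnacky,quercus_evergreen,b0,-2.2198
chojnacky,quercus_evergreen,b1,2.441
chojnacky,quercus_evergreen,dbh_max_sampled,80
chojnacky,quercus_deciduous,b0,-2.0705
chojnacky,quercus_deciduous,b1,2.441
chojnacky,quercus_deciduous,dbh_max_sampled,75
chojnacky,fagaceae_evergreen,b0,-2.2198
chojnacky,fagaceae_evergreen,b1,2.441
chojnacky,fagaceae_evergreen,dbh_max_sampled,60
chojnacky,lauraceae,b0,-2.12
chojnacky,lauraceae,b1,2.41
chojnacky,lauraceae,dbh_max_sampled,58
chojnacky,ericaceae,b0,-2.5932
chojnacky,ericaceae,b1,2.5349
chojnacky,ericaceae,dbh_max_sampled,56
chojnacky,acer,b0,-2.047
chojnacky,acer,b1,2.3852
chojnacky,acer,dbh_max_sampled,66
chojnacky,alnus,b0,-2.7765
chojnacky,alnus,b1,2.5346
chojnacky,alnus,dbh_max_sampled,70
crm,cedar_larch,vol_a,0.004
crm,cedar_larch,vol_b,0.000024
crm,cedar_larch,bark_r0,0.16
crm,cedar_larch,bark_r1,-0.08
crm,cedar_larch,branch_r0,0.28
crm,cedar_larch,branch_r1,-0.05
crm,cedar_larch,specific_gravity,0.36
crm,cedar_larch,dbh_max_sampled,220
crm,douglas_fir,vol_a,0.005
crm,douglas_fir,vol_b,0.000025
crm,douglas_fir,bark_r0,0.2
crm,douglas_fir,bark_r1,-0.1
crm,douglas_fir,branch_r0,0.3
crm,douglas_fir,branch_r1,-0.06
crm,douglas_fir,specific_gravity,0.45
crm,douglas_fir,dbh_max_sampled,190
crm,true_fir_hemlock,vol_a,0.005
crm,true_fir_hemlock,vol_b,0.000023
crm,true_fir_hemlock,bark_r0,0.18
crm,true_fir_hemlock,bark_r1,-0.09
crm,true_fir_hemlock,branch_r0,0.32
crm,true_fir_hemlock,branch_r1,-0.07
crm,true_fir_hemlock,specific_gravity,0.4
crm,true_fir_hemlock,dbh_max_sampled,200
crm,pine,vol_a,0.004
crm,pine,vol_b,0.0000225
crm,pine,bark_r0,0.22
crm,pine,bark_r1,-0.11
crm,pine,branch_r0,0.34
crm,pine,branch_r1,-0.08
crm,pine,specific_gravity,0.4
crm,pine,dbh_max_sampled,170
crm,spruce,vol_a,0.004
crm,spruce,vol_b,0.000023
crm,spruce,bark_r0,0.18
crm,spruce,bark_r1,-0.09
crm,spruce,branch_r0,0.33
crm,spruce,branch_r1,-0.07
crm,spruce,specific_gravity,0.37
crm,spruce,dbh_max_sampled,95
crm,aspen_alder,vol_a,0.003
crm,aspen_alder,vol_b,0.0000195
crm,aspen_alder,bark_r0,0.24
crm,aspen_alder,bark_r1,-0.12
crm,aspen_alder,branch_r0,0.5
crm,aspen_alder,branch_r1,-0.12
crm,aspen_alder,specific_gravity,0.38
crm,aspen_alder,dbh_max_sampled,65
crm,soft_maple_birch,vol_a,0.003
crm,soft_maple_birch,vol_b,0.00002
crm,soft_maple_birch,bark_r0,0.22
crm,soft_maple_birch,bark_r1,-0.11
crm,soft_maple_birch,branch_r0,0.55
crm,soft_maple_birch,branch_r1,-0.12
crm,soft_maple_birch,specific_gravity,0.46
crm,soft_maple_birch,dbh_max_sampled,62
crm,mixed_hardwood,vol_a,0.003
crm,mixed_hardwood,vol_b,0.0000195
crm,mixed_hardwood,bark_r0,0.23
crm,mixed_hardwood,bark_r1,-0.11
crm,mixed_hardwood,branch_r0,0.52
crm,mixed_hardwood,branch_r1,-0.11
crm,mixed_hardwood,specific_gravity,0.5
crm,mixed_hardwood,dbh_max_sampled,55
crm,hard_maple_oak_hickory_beech,vol_a,0.003
crm,hard_maple_oak_hickory_beech,vol_b,0.0000195
crm,hard_maple_oak_hickory_beech,bark_r0,0.24
crm,hard_maple_oak_hickory_beech,bark_r1,-0.12
crm,hard_maple_oak_hickory_beech,branch_r0,0.58
crm,hard_maple_oak_hickory_beech,branch_r1,-0.12
crm,hard_maple_oak_hickory_beech,specific_gravity,0.6
crm,hard_maple_oak_hickory_beech,dbh_max_sampled,70
crm,woodland,vol_a,0.002
crm,woodland,vol_b,0.000018
crm,woodland,bark_r0,0.25
crm,woodland,bark_r1,-0.12
crm,woodland,branch_r0,0.6
crm,woodland,branch_r1,-0.12
crm,woodland,specific_gravity,0.58
crm,woodland,dbh_max_sampled,75
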