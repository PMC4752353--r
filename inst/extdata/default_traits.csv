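name,shape_model,mean_length_mm,mean_width_mm,fixed_volume_cm3,mass_a,mass_b,group_mean_mass_mg,is_vertebrate_or_carrion,volume_overestimate
Formicidae,prolate_spheroid,4,1.2,NA,0.031,2.64,1.1,FALSE,FALSE
Coleoptera,prolate_spheroid,8,3,NA,0.042,2.7,12.5,FALSE,FALSE
Isopoda,fixed_displacement,9,4.5,0.12,0.048,2.55,9.8,FALSE,FALSE
Gastropoda,fixed_displacement,11,8,0.9,NA,NA,35,FALSE,TRUE
Crustacea_other,fixed_displacement,22,16,2.5,NA,NA,110,FALSE,TRUE
Diplopoda,cylinder,20,3,NA,0.026,2.45,18,FALSE,FALSE
Diptera,prolate_spheroid,6,2,NA,0.02,2.48,2.1,FALSE,FALSE
Hymenoptera,prolate_spheroid,7,2,NA,0.025,2.52,3.4,FALSE,FALSE
Heteroptera,prolate_spheroid,6,2.5,NA,0.035,2.6,6.2,FALSE,FALSE
Homoptera,prolate_spheroid,4,1.5,NA,0.022,2.5,1.8,FALSE,FALSE
Araneae,prolate_spheroid,5,2.5,NA,0.055,2.46,4.9,FALSE,FALSE
Insect_larvae,cylinder,10,2,NA,0.018,2.4,5.6,FALSE,FALSE
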