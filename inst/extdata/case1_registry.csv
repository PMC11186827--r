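hazard_id,hazard_class,route,evidence_kind,compartment,value,units,basis
(fluoro)quinolones,chemical,environment,occurrence_concentration,raw cattle manure,7900,ng/g dm,
(fluoro)quinolones,chemical,environment,occurrence_concentration,raw poultry manure,92696,ng/g dm,
(fluoro)quinolones,chemical,environment,occurrence_concentration,raw swine manure,12099,ng/g dm,
(fluoro)quinolones,chemical,environment,dt50,manure:cattle solid,564,days,
(fluoro)quinolones,chemical,environment,dt50,manure:cattle semi-solid,226,days,
(fluoro)quinolones,chemical,environment,dt50,manure:cattle liquid,82,days,
(fluoro)quinolones,chemical,environment,dt50,manure:pig,75,days,
(fluoro)quinolones,chemical,environment,dt50,manure:broiler,121,days,
(fluoro)quinolones,chemical,environment,dt50,soil:sand,182,days,
(fluoro)quinolones,chemical,environment,dt50,soil:clay,97,days,
(fluoro)quinolones,chemical,environment,log_koc,,2.9,,
(fluoro)quinolones,chemical,environment,chronic_level,,H,,
(fluoro)quinolones,chemical,environment,antibiotic_choice_class,,3,,
macrolides,chemical,environment,occurrence_concentration,raw cattle manure,40,ng/g dm,
macrolides,chemical,environment,occurrence_concentration,raw poultry manure,3836,ng/g dm,
macrolides,chemical,environment,occurrence_concentration,raw swine manure,6927,ng/g dm,
macrolides,chemical,environment,dt50,manure:cattle solid,2,days,
macrolides,chemical,environment,dt50,manure:cattle semi-solid,94,days,
macrolides,chemical,environment,dt50,manure:cattle liquid,79,days,
macrolides,chemical,environment,dt50,manure:pig,50,days,
macrolides,chemical,environment,dt50,manure:broiler,61,days,
macrolides,chemical,environment,dt50,soil:sand,56,days,
macrolides,chemical,environment,dt50,soil:clay,73,days,
macrolides,chemical,environment,log_koc,,2.0,,
macrolides,chemical,environment,chronic_level,,L,,
macrolides,chemical,environment,antibiotic_choice_class,,3,,
sulphonamides,chemical,environment,occurrence_concentration,raw cattle manure,1277,ng/g dm,
sulphonamides,chemical,environment,occurrence_concentration,raw poultry manure,10591,ng/g dm,
sulphonamides,chemical,environment,occurrence_concentration,raw swine manure,6277,ng/g dm,
sulphonamides,chemical,environment,dt50,manure:cattle solid,1,days,
sulphonamides,chemical,environment,dt50,manure:cattle semi-solid,3,days,
sulphonamides,chemical,environment,dt50,manure:cattle liquid,12,days,
sulphonamides,chemical,environment,dt50,manure:pig,2,days,
sulphonamides,chemical,environment,dt50,manure:broiler,3,days,
sulphonamides,chemical,environment,dt50,soil:sand,1,days,
sulphonamides,chemical,environment,dt50,soil:clay,1,days,
sulphonamides,chemical,environment,log_koc,,0.5,,
sulphonamides,chemical,environment,chronic_level,,L,,
sulphonamides,chemical,environment,antibiotic_choice_class,,1,,
tetracyclines,chemical,environment,occurrence_concentration,raw cattle manure,40805,ng/g dm,
tetracyclines,chemical,environment,occurrence_concentration,raw poultry manure,30166,ng/g dm,
tetracyclines,chemical,environment,occurrence_concentration,raw swine manure,89639,ng/g dm,
tetracyclines,chemical,environment,dt50,manure:cattle solid,76,days,
tetracyclines,chemical,environment,dt50,manure:cattle semi-solid,57,days,
tetracyclines,chemical,environment,dt50,manure:cattle liquid,32,days,
tetracyclines,chemical,environment,dt50,manure:pig,14,days,
tetracyclines,chemical,environment,dt50,manure:broiler,33,days,
tetracyclines,chemical,environment,dt50,soil:sand,9,days,
tetracyclines,chemical,environment,dt50,soil:clay,1,days,
tetracyclines,chemical,environment,log_koc,,3.0,,
tetracyclines,chemical,environment,chronic_level,,L,,
tetracyclines,chemical,environment,antibiotic_choice_class,,2,,
E. coli,microbial,environment,occurrence_concentration,raw cattle manure,1.3e8,cfu/g dm,
E. coli,microbial,environment,occurrence_concentration,raw poultry manure,2.2e7,cfu/g dm,
E. coli,microbial,environment,occurrence_concentration,raw swine manure,4.7e4,cfu/g dm,
E. coli,microbial,environment,log_reduction,manure-amended soil,12.6,days/log,
E. coli,microbial,environment,waiting_time,,60,days,
E. coli,microbial,environment,transfer_level,,M,,
E. coli,microbial,environment,daly,,0.065,DALY/case,
Salmonella spp.,microbial,environment,occurrence_concentration,raw cattle manure,3.1e5,cfu/g dm,
Salmonella spp.,microbial,environment,occurrence_concentration,raw poultry manure,1.4e4,cfu/g dm,
Salmonella spp.,microbial,environment,occurrence_concentration,raw swine manure,3.7e3,cfu/g dm,
Salmonella spp.,microbial,environment,log_reduction,manure-amended soil,15.9,days/log,
Salmonella spp.,microbial,environment,waiting_time,,60,days,
Salmonella spp.,microbial,environment,persistence_level,,L,,
Salmonella spp.,microbial,environment,transfer_level,,M,,
Salmonella spp.,microbial,environment,daly,,0.039,DALY/case,
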