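hazard_id,hazard_class,route,evidence_kind,compartment,value,units,basis
DON,chemical,environment,occurrence_exceedance,wheat at harvest (short chain),0.062,,
DON,chemical,environment,persistence_level,,H,,
DON,chemical,environment,transfer_level,,H,,
DON,chemical,environment,hbgv,,1,ug/kg bw,per_day
ZEA,chemical,environment,occurrence_exceedance,wheat at harvest (short chain),0.067,,
ZEA,chemical,environment,persistence_level,,H,,
ZEA,chemical,environment,transfer_level,,H,,
ZEA,chemical,environment,hbgv,,0.25,ug/kg bw,per_day
T-2 and HT-2,chemical,environment,occurrence_exceedance,wheat at harvest (short chain),0.0,,
T-2 and HT-2,chemical,environment,persistence_level,,H,,
T-2 and HT-2,chemical,environment,transfer_level,,H,,
T-2 and HT-2,chemical,environment,hbgv,,0.02,ug/kg bw,per_day
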