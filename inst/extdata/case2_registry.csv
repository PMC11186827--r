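hazard_id,hazard_class,route,evidence_kind,compartment,value,units,basis
dioxins and PCBs,chemical,accumulation,occurrence_level,household waste,L,,
dioxins and PCBs,chemical,accumulation,occurrence_level,manure,M,,
dioxins and PCBs,chemical,accumulation,baf,,2,,
dioxins and PCBs,chemical,accumulation,hbgv,,2e-6,ug/kg bw,per_week
tetracyclines/veterinary drugs,chemical,accumulation,occurrence_level,household waste,L,,
tetracyclines/veterinary drugs,chemical,accumulation,occurrence_level,manure,H,,
tetracyclines/veterinary drugs,chemical,accumulation,accumulation_level,,L,,
tetracyclines/veterinary drugs,chemical,accumulation,severity_level,,L,,
pesticides,chemical,accumulation,occurrence_level,household waste,L,,
pesticides,chemical,accumulation,occurrence_level,manure,L,,
pesticides,chemical,accumulation,accumulation_level,,L,,
pesticides,chemical,accumulation,severity_level,,L,,
cadmium,chemical,accumulation,occurrence_level,household waste,M,,
cadmium,chemical,accumulation,occurrence_level,manure,L,,
cadmium,chemical,accumulation,baf,,20,,
cadmium,chemical,accumulation,hbgv,,2.5,ug/kg bw,per_week
lead,chemical,accumulation,occurrence_level,household waste,H,,
lead,chemical,accumulation,occurrence_level,manure,L,,
lead,chemical,accumulation,baf,,2.3,,
lead,chemical,accumulation,hbgv,,0.63,ug/kg bw,per_day
aflatoxin B1,chemical,accumulation,occurrence_level,household waste,L,,
aflatoxin B1,chemical,accumulation,occurrence_level,manure,L,,
aflatoxin B1,chemical,accumulation,accumulation_level,,L,,
aflatoxin B1,chemical,accumulation,hbgv,,0.4,ug/kg bw,per_day
deoxynivalenol,chemical,accumulation,occurrence_level,household waste,L,,
deoxynivalenol,chemical,accumulation,occurrence_level,manure,L,,
deoxynivalenol,chemical,accumulation,accumulation_level,,L,,
deoxynivalenol,chemical,accumulation,hbgv,,1,ug/kg bw,per_day
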