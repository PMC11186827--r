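hazard_id,printed_priority
dioxins and PCBs,M
tetracyclines/veterinary drugs,L
pesticides,L
cadmium,H
lead,H
aflatoxin B1,L
deoxynivalenol,L
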