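# Default classification thresholds.  Missing keys fall back to the
# package defaults; listing them all here documents the stated values.
dt50_bounds: 30, 100
koc_bounds: 1.0, 2.0
baf_bounds: 1.0, 5.0
chem_conc_bounds: 10000, 20000
micro_conc_bounds: 1000000, 10000000
exceedance_threshold: 0.03
hbgv_daily_cutoff: 10
daly_bounds: 0.01, 0.1
log_reduction_bounds: 2, 4
occurrence_collapse: mean
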