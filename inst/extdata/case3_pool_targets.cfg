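# Summary statistics of mycotoxin concentrations (ug/kg) measured in
# 293 commercial Dutch wheat fields at harvest, 2009-2018.  Floors are
# the censoring values visible in the scenario minima.
[DON]
median: 60
mean: 411
max: 15400
frac_above_limit: 0.061
limit: 1250
limit_kind: maximum_limit
floor: 25
size: 293

[ZEA]
median: 25
mean: 65
max: 2000
frac_above_limit: 0.069
limit: 100
limit_kind: maximum_limit
floor: 25
size: 293

[T-2 and HT-2]
median: 10
mean: 11.7
max: 66
frac_above_limit: 0.0
limit: 100
limit_kind: guidance
floor: 10
size: 293
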