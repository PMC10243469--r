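region,participants,population_pct
East Midlands,53,7.23
East of England,43,9.25
London,62,12.97
North East,42,4.12
North West,78,11.14
Northern Ireland,8,2.83
Scotland,30,8.38
South East,67,13.63
South West,82,8.37
Wales,20,4.82
West Midlands,57,8.91
Yorkshire and The Humber,57,8.36
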