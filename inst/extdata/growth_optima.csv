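# Optimal OD600 and colony counts of the wild strains after 120 h of YPD
# culture (n = 3, mean +/- SE).
strain,od600,od_se,cfu,cfu_se
RmTun15,24.36,0.37,311,11
YlTun15,24.14,0.31,205,12
TaTun15,27.36,0.10,247,13
DhTun2015,21.92,0.84,222,10
CtTun15,28.21,0.71,213,22
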