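# Colony counts (CFU) after EMS exposure at the optimal dose (75 mM, 50 ul);
# time_min = 0 is the untreated control. "-" encodes "no colony on the plate"
# (structural zero, lethal). Values are replicate means (n = 6) +/- SE.
strain,time_min,cfu_mean,cfu_se
YlTun15,0,205,12
YlTun15,15,178,17
YlTun15,30,89,15
YlTun15,45,66,1
YlTun15,60,23,3
RmTun15,0,311,19
RmTun15,15,272,17
RmTun15,30,132,11
RmTun15,45,98,7
RmTun15,60,36,3
TaTun15,0,247,13
TaTun15,15,193,7
TaTun15,30,95,11
TaTun15,45,49,3
TaTun15,60,19,5
DhTun2015,0,222,10
DhTun2015,15,173,4
DhTun2015,30,82,6
DhTun2015,45,7,5
DhTun2015,60,-,
CtTun15,0,213,22
CtTun15,15,97,17
CtTun15,30,13,6
CtTun15,45,-,
CtTun15,60,-,
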