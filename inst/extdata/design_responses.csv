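# EMS dose/volume screening responses: 3x3 full factorial (run ids follow the
# published experiment numbering; factor settings in design run order:
# 1=(75,100) 2=(100,50) 3=(25,15) 4=(25,50) 5=(100,100) 6=(75,15) 7=(100,15)
# 8=(25,100) 9=(75,50); conc mM, vol ul). Values are run means (n=3).
# 'uncertain' flags cells whose transcription from the typographically
# run-together source table is ambiguous; fitting restricted to clean columns.
strain,run,cfu,od,uncertain
YlTun15,1,23,19.41,FALSE
YlTun15,2,21,20.16,FALSE
YlTun15,3,182,20.12,FALSE
YlTun15,4,163,20.47,FALSE
YlTun15,5,0,0,FALSE
YlTun15,6,175,20.14,FALSE
YlTun15,7,81,18.95,FALSE
YlTun15,8,79,19.48,FALSE
YlTun15,9,89,21.8,FALSE
TaTun15,1,19,21.93,FALSE
TaTun15,2,29,21.26,FALSE
TaTun15,3,222,21,TRUE
TaTun15,4,187,21.92,FALSE
TaTun15,5,0,0,FALSE
TaTun15,6,193,21.18,FALSE
TaTun15,7,161,19.38,FALSE
TaTun15,8,130,20.38,FALSE
TaTun15,9,95,22.41,FALSE
RmTun15,1,31,9.44,TRUE
RmTun15,2,31,19.57,FALSE
RmTun15,3,287,15.38,FALSE
RmTun15,4,17,16.12,TRUE
RmTun15,5,0,0,FALSE
RmTun15,6,272,20.94,FALSE
RmTun15,7,117,16.56,FALSE
RmTun15,8,121,18.44,FALSE
RmTun15,9,132,22.82,FALSE
DhTun2015,1,0,0,FALSE
DhTun2015,2,5,15.68,FALSE
DhTun2015,3,200,13.95,FALSE
DhTun2015,4,171,18.12,FALSE
DhTun2015,5,0,0,FALSE
DhTun2015,6,173,19.63,FALSE
DhTun2015,7,3,14.21,TRUE
DhTun2015,8,94,20.31,FALSE
DhTun2015,9,82,21.3,FALSE
CtTun15,1,0,0,FALSE
CtTun15,2,0,0,FALSE
CtTun15,3,191,16.3,FALSE
CtTun15,4,163,17.68,FALSE
CtTun15,5,0,0,FALSE
CtTun15,6,97,24.68,FALSE
CtTun15,7,48,23.15,FALSE
CtTun15,8,87,20.65,FALSE
CtTun15,9,113,25.53,FALSE
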