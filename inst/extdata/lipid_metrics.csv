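# Lipid yield L (g/100 g wet biomass), lipid content LC (w%) and final lipid
# productivity LP (mg/ml/h) for wild and mutated strains (n = 9, +/- SE).
# bp (mg/ml/h) is the biomass productivity where one was reported.
# NOTE: the reported LP values are not reproducible from bp and L via
# LP = bp * L / 100 (e.g. wild YlTun15: 0.37 * 10.32 / 100 = 0.038 vs
# reported 0.090); 'lp_consistent' records whether the stated formula
# reproduces the reported LP to within 0.005 where bp is available.
strain,variant,yield,yield_se,content,content_se,lp,bp,lp_consistent
YlTun15,wild,10.32,0.21,42.88,0.14,0.090,0.37,FALSE
YlTun15,MY-1,11.81,0.08,46.41,1.35,0.099,,
YlTun15,MY-2,13.22,0.11,51.74,0.17,0.130,0.61,FALSE
YlTun15,MY-3,10.22,14,39.68,0.13,0.099,,
YlTun15,MY-4,10.26,0.11,41.24,0.84,0.082,,
RmTun15,wild,8.18,0.02,36.83,0.21,0.073,0.37,FALSE
RmTun15,MR-1,11.13,0.16,35.39,0.11,0.113,,
RmTun15,MR-2,11.82,0.33,46.98,0.31,0.130,0.68,FALSE
RmTun15,MR-3,10.63,0.14,38.08,0.41,0.086,,
RmTun15,MR-4,9.61,0.27,38.89,0.24,0.080,,
TaTun15,wild,3.67,0.44,21.80,1.10,0.037,0.27,FALSE
TaTun15,MT-1,4.86,0.08,25.98,0.21,0.049,,
TaTun15,MT-2,5.73,0.46,29.94,0.11,0.059,0.29,FALSE
TaTun15,MT-3,5.75,0.10,31.47,0.42,0.058,,
TaTun15,MT-4,5.84,0.10,32.02,0.27,0.059,,
DhTun2015,wild,2.32,0.09,19.76,0.81,0.018,0.16,FALSE
DhTun2015,MD-1,2.18,0.08,20.14,0.18,0.020,,
DhTun2015,MD-2,2.07,0.17,20.57,0.33,0.019,0.19,FALSE
DhTun2015,MD-3,1.36,0.19,12.25,0.19,0.011,,
CtTun15,wild,2.53,0.16,25.63,0.85,0.022,0.15,FALSE
CtTun15,MC-1,3.21,0.09,30.77,0.61,0.027,,
CtTun15,MC-2,2.76,0.09,27.82,0.32,0.024,0.21,FALSE
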