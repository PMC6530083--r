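# Reported biodiesel physical properties for the screened strains (n = 6,
# mean +/- SE): SV (mg KOH), IV (gI2/100 g), CN, HHV (MJ/kg), CFPP (degC),
# kinematic viscosity kv (mm2/s), density D (g/cm3), oxidative stability
# OS (h). Empty SE fields were not reported.
strain,variant,sv,sv_se,iv,iv_se,cn,cn_se,hhv,hhv_se,cfpp,cfpp_se,kv,kv_se,density,os,os_se
RmTun15,wild,216.91,5.33,113.26,3.38,45.26,2.62,38.99,0.24,-14.92,0.37,3.87,0.11,0.95,6.87,0.02
RmTun15,MR-2,159.66,0.84,107.76,1.14,53.01,0.43,41.27,0.55,-7.37,0.31,3.80,0.21,0.85,21.71,2.17
RmTun15,MR-3,148.80,6.63,101.26,4.07,57.30,2.56,41.81,0.33,-7.62,0.33,3.80,0.64,0.85,17.78,3.32
TaTun15,wild,211.40,5.02,83.10,0.45,50.96,4.34,39.52,0.08,16.40,0.20,4.35,0.09,0.85,6.36,0.03
TaTun15,MT-2,151.08,3.42,60.04,4.05,67.15,1.29,42.43,0.15,1.07,,3.85,,0.85,20.11,1.11
TaTun15,MT-3,142.49,1.17,96.21,2.47,60.08,0.94,42.14,0.08,-4.71,0.87,4.03,,0.85,21.78,3.41
YlTun15,wild,213.12,0.06,48.53,1.54,59.53,0.39,39.96,0.02,31.97,0.50,4.03,0.01,1.1,18.81,0.86
YlTun15,MY-2,195.64,1.28,160.13,4.83,33.37,1.13,39.01,0.06,-6.80,0.92,3.46,0.22,0.85,16.88,0.99
YlTun15,MY-3,194.75,0.76,166.31,6.24,31.92,1.49,38.95,0.06,-3.91,0.55,3.69,,0.85,17.86,1.08
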