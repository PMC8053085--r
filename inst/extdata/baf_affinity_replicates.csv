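label,method,ligand,replicate,kd_printed
BAF WT,fluorescence,48 nt dsDNA,1,2.10E-09
BAF WT,fluorescence,48 nt dsDNA,2,1.40E-09
BAF WT,fluorescence,48 nt dsDNA,3,4.20E-09
BAF WT,fluorescence,48 nt dsDNA,4,2.20E-09
BAF WT,fluorescence,48 nt dsDNA,5,2.80E-09
BAF A12T,fluorescence,48 nt dsDNA,1,1.60E-09
BAF A12T,fluorescence,48 nt dsDNA,2,1.70E-09
BAF A12T,fluorescence,48 nt dsDNA,3,3.70E-09
BAF A12T,fluorescence,48 nt dsDNA,4,3.00E09
BAF S4E,fluorescence,48 nt dsDNA,1,17.0E-06
BAF S4E,fluorescence,48 nt dsDNA,2,13.0E-06
pBAF,fluorescence,48 nt dsDNA,1,12.0E-06
pBAF,fluorescence,48 nt dsDNA,2,9.40E-06
BAF WT,itc,48 nt dsDNA,1,37.7E-09
BAF WT,itc,48 nt dsDNA,2,44.4E-09
BAF A12T,itc,48 nt dsDNA,1,37.0E-09
BAF A12T,itc,48 nt dsDNA,2,20.6E-09
BAF WT,itc,21 nt dsDNA,1,0.17E-06
BAF WT,itc,21 nt dsDNA,2,0.11E-06
BAF A12T,itc,21 nt dsDNA,1,0.30E-06
BAF A12T,itc,21 nt dsDNA,2,0.21E-06
BAF WT,itc,7 nt dsDNA,1,1.00E-06
BAF WT,itc,7 nt dsDNA,2,2.10E-06
BAF A12T,itc,7 nt dsDNA,1,1.70E-06
BAF A12T,itc,7 nt dsDNA,2,0.92E-06
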