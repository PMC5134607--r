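site,ud,ud_pm,sd,sd_pm,dd,dd_pm,rd,rd_pm,gsl,gsl_pm,min_gcc,max_gcc,range_gcc
Wet Meadow,127,0.5,156,0.5,188,2,257,1,130,1,0.327,0.389,0.062
Mesic Meadow,113,15,150,1,180,2,269,3,157,14,0.329,0.369,0.040
Meadow Sagebrush Canopy,82,1,157,1,189,2,264,2,181,2,0.329,0.354,0.025
Upland Sagebrush Canopy,108,10,163,7,207,11,265,5,157,14,0.312,0.334,0.022
Upland Pinyon,116,2,165,2,231,4,347,3,230,4,0.333,0.352,0.019
Upland Juniper,111,2,173,2,223,4,334,4,224,4,0.321,0.361,0.040
Upland Sagebrush Steppe,99,22,167,17,194,22,269,8,170,28,0.311,0.333,0.022
Upland Sagebrush Interspace,119,24,144,14,223,5,265,10,146,15,0.308,0.324,0.016
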