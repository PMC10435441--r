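# Molar extinction of oxy- and deoxy-hemoglobin, Prahl-class approximation.
# Columns: vacuum wavelength (nm), epsilon (1/(cm*M)) for HbO2 and Hb.
# Anchored on the standard compilation through 1000 nm; smooth (and optically
# negligible next to water) taper beyond. Linear interpolation intended.
wavelength_nm,eps_hbo2,eps_hb
450,62816,103292
460,44480,91136
480,26629,16156
500,20932,20862
510,20035,24300
520,24202,25773
530,39956,35464
540,53236,46592
550,43016,53412
555,40092,55540
560,32613,53788
570,44496,49868
577,60400,37020
590,14700,26600
600,3200,14677
610,1506,10880
620,942,6510
635,610,4920
650,368,3750
660,320,3227
680,277,2407
700,290,1794
720,334,1300
750,518,1405
775,700,1200
800,816,761
820,916,693
850,1058,691
880,1154,726
900,1198,761
950,1200,653
1000,1058,550
1100,780,480
1200,600,420
1300,500,370
1400,450,330
1500,400,310
1600,360,300
1750,320,290
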