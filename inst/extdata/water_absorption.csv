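# Pure water absorption spectrum, Hale-Querry/Segelstein-class approximation.
# Columns: vacuum wavelength (nm), absorption coefficient (1/cm).
# Local maxima at the 975 and 1448 nm water bands; linear interpolation intended.
wavelength_nm,mu_a_per_cm
450,0.00025
475,0.00036
500,0.00058
525,0.00120
550,0.00180
575,0.00200
600,0.00220
625,0.00280
650,0.00320
675,0.00430
700,0.00600
725,0.01590
740,0.02660
750,0.02610
775,0.02390
800,0.02000
825,0.02820
850,0.04330
875,0.05580
900,0.06790
920,0.11000
940,0.26800
950,0.38800
960,0.43300
970,0.47200
975,0.48700
980,0.48300
990,0.45800
1000,0.36300
1020,0.27000
1064,0.14400
1100,0.17400
1150,0.65000
1180,0.95000
1200,1.04000
1220,0.98000
1250,0.88000
1300,1.15000
1350,2.80000
1400,12.40000
1420,21.00000
1440,28.50000
1448,29.50000
1460,28.00000
1480,24.00000
1500,20.50000
1550,11.80000
1600,6.70000
1650,5.30000
1700,5.50000
1750,7.60000
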