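depth_cm,o2_uM,no3_uM,no2_uM,nh4_uM,porosity
0,15.0108377431432,11.9858528157839,bd,bd,0.7
10,6.31315314916461,10.5341522259714,bd,bd,0.7
20,2.23900167669806,9.09981294521575,0.196886054768703,bd,0.7
30,bd,7.70248748363518,0.338734779411785,bd,0.7
40,bd,6.61707077029522,0.611583702394265,bd,0.7
50,bd,5.48051271515058,0.766241536972547,bd,0.7
60,bd,4.55481885117171,1.13845063075972,bd,0.7
70,bd,3.60549931590234,1.6578265478196,bd,0.7
80,bd,2.82169301315325,2.15915294675073,bd,0.7
90,bd,2.30305659362489,2.86524468763982,bd,0.7
100,bd,1.66977400846216,3.20132584914997,bd,0.7
110,bd,1.12862972913633,3.33014824454783,bd,0.7
120,bd,0.656704808543137,2.79868480325299,bd,0.7
130,bd,bd,2.38098940276029,bd,0.7
140,bd,bd,1.78481329840087,bd,0.7
150,bd,bd,1.35405490969424,bd,0.7
160,bd,bd,1.02012244431578,bd,0.7
170,bd,bd,0.845768416955201,bd,0.7
180,bd,bd,0.675867561244859,0.102739881657232,0.7
190,bd,bd,0.532735595576888,0.994772398119377,0.7
200,bd,bd,0.440973251052178,3.61514744944719,0.7
210,bd,bd,0.30049630132639,8.15989108391494,0.7
220,bd,bd,0.168574399340047,13.643121700451,0.7
230,bd,bd,0.117285716150357,19.3844239567146,0.7
240,bd,bd,bd,24.9861232186269,0.7
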