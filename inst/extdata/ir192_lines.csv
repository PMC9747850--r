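# Ir-192 photon emission line list (energy MeV, photons per decay).
# Compiled from the evaluated decay data distributed by the National Nuclear
# Data Center (gamma lines of the beta- branch to Pt-192 and the EC branch to
# Os-192, plus Pt/Os K and L X-rays from internal conversion and electron
# capture). Intensities of minor lines are approximate in the last digit;
# this file is a compilation, not a verbatim copy of any evaluated file.
# Lines span 7.822 keV (Os Ll X-ray) to 1.378 MeV.
0.0078220 0.00088
0.0089110 0.01350
0.0094420 0.01650
0.0105100 0.00620
0.0110700 0.01310
0.0129400 0.00170
0.0614860 0.00119
0.0630000 0.00203
0.0651220 0.02630
0.0668310 0.04460
0.0712000 0.00071
0.0757490 0.01570
0.0778310 0.00420
0.1363430 0.00199
0.2013110 0.00473
0.2057940 0.03340
0.2832670 0.00266
0.2959570 0.28710
0.3084550 0.29700
0.3165060 0.82860
0.3744850 0.00726
0.4164690 0.00670
0.4205200 0.00069
0.4680690 0.47840
0.4845750 0.03189
0.4890600 0.00438
0.5885810 0.04522
0.5934900 0.00042
0.6044110 0.08216
0.6124620 0.05340
0.7038500 0.00005
0.7658000 0.00001
0.8845370 0.00291
1.0614800 0.00053
1.0899600 0.00001
1.3780000 0.00001
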