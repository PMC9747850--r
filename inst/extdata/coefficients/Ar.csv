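# element Ar (Z=18, A=39.948)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,6.17969725e+01,6.16264424e+01
1.05118235e-02,5.35772489e+01,5.34071987e+01
1.10498434e-02,4.64327170e+01,4.62631682e+01
1.16154003e-02,4.02255371e+01,4.00565119e+01
1.22099038e-02,3.48351416e+01,3.46666633e+01
1.28348354e-02,3.01562855e+01,2.99883780e+01
1.34917525e-02,2.60969096e+01,2.59295977e+01
1.41822921e-02,2.25690873e+01,2.24023966e+01
1.49081752e-02,1.95053829e+01,1.93393400e+01
1.56712107e-02,1.68549006e+01,1.66895329e+01
1.64733001e-02,1.45626750e+01,1.43980109e+01
1.73164423e-02,1.25809463e+01,1.24170148e+01
1.82027386e-02,1.08682290e+01,1.07050603e+01
1.91343975e-02,9.38850038e+00,9.22612536e+00
2.01137410e-02,8.11049128e+00,7.94894176e+00
2.11432096e-02,7.00706836e+00,6.84637699e+00
2.22253688e-02,6.05469501e+00,5.89489528e+00
2.33629154e-02,5.23296165e+00,5.07408786e+00
2.45586844e-02,4.52417632e+00,4.36626359e+00
2.58156556e-02,3.91300823e+00,3.75609240e+00
2.71369616e-02,3.38615937e+00,3.23027700e+00
2.85258951e-02,2.93212250e+00,2.77731087e+00
2.99859175e-02,2.54098252e+00,2.38727952e+00
3.15206672e-02,2.20412181e+00,2.05156590e+00
3.31339691e-02,1.91408624e+00,1.76271642e+00
3.48298436e-02,1.66443043e+00,1.51428613e+00
3.66125169e-02,1.44958310e+00,1.30070415e+00
3.84864316e-02,1.26473034e+00,1.11715686e+00
4.04562577e-02,1.10571404e+00,9.59486380e-01
4.25269041e-02,9.68943907e-01,8.24102523e-01
4.47035311e-02,8.51321007e-01,7.07906390e-01
4.69915629e-02,7.50171508e-01,6.08224066e-01
4.93967017e-02,6.63189204e-01,5.22749159e-01
5.19249410e-02,5.88385711e-01,4.49492979e-01
5.45825816e-02,5.24047303e-01,3.86741378e-01
5.73762465e-02,4.68697535e-01,3.33017362e-01
6.03128978e-02,4.21064873e-01,2.87048724e-01
6.33998537e-02,3.80054687e-01,2.47740026e-01
6.66448073e-02,3.44725006e-01,2.14148360e-01
7.00558453e-02,3.14265559e-01,1.85462387e-01
7.36414682e-02,2.87979653e-01,1.60984209e-01
7.74106118e-02,2.65268504e-01,1.40113709e-01
8.13726689e-02,2.45617706e-01,1.22335017e-01
8.55375135e-02,2.28585543e-01,1.07204829e-01
8.99155246e-02,2.13792895e-01,9.43423155e-02
9.45176126e-02,2.00914534e-01,8.34204233e-02
9.93552463e-02,1.89671601e-01,7.41583643e-02
1.04440482e-01,1.79825135e-01,6.63151445e-02
1.09785991e-01,1.71170477e-01,5.96839851e-02
1.15405096e-01,1.63532458e-01,5.40875165e-02
1.21311800e-01,1.56761247e-01,4.93736396e-02
1.27520824e-01,1.50728777e-01,4.54119622e-02
1.34047639e-01,1.45325664e-01,4.20907336e-02
1.40908513e-01,1.40458560e-01,3.93142067e-02
1.48120542e-01,1.36047869e-01,3.70003705e-02
1.55701700e-01,1.32025784e-01,3.50790003e-02
1.63670879e-01,1.28334600e-01,3.34899827e-02
1.72047939e-01,1.24925262e-01,3.21818764e-02
1.80853757e-01,1.21756111e-01,3.11106764e-02
1.90110278e-01,1.18791818e-01,3.02387529e-02
1.99840569e-01,1.16002459e-01,2.95339404e-02
2.10068880e-01,1.13362720e-01,2.89687561e-02
2.20820699e-01,1.10851221e-01,2.85197289e-02
2.32122822e-01,1.08449931e-01,2.81668243e-02
2.44003413e-01,1.06143664e-01,2.78929503e-02
2.56492082e-01,1.03919658e-01,2.76835343e-02
2.69619950e-01,1.01767196e-01,2.75261600e-02
2.83419733e-01,9.96773024e-02,2.74102558e-02
2.97925822e-01,9.76424676e-02,2.73268280e-02
3.13174366e-01,9.56564205e-02,2.72682318e-02
3.29203366e-01,9.37139327e-02,2.72279756e-02
3.46052769e-01,9.18106523e-02,2.72005528e-02
3.63764564e-01,8.99429618e-02,2.71812981e-02
3.82382889e-01,8.81078592e-02,2.71662648e-02
4.01954145e-01,8.63028560e-02,2.71521197e-02
4.22527103e-01,8.45258921e-02,2.71360534e-02
4.44153034e-01,8.27752642e-02,2.71157039e-02
4.66885831e-01,8.10495654e-02,2.70890918e-02
4.90782146e-01,7.93476352e-02,2.70545648e-02
5.15901531e-01,7.76685177e-02,2.70107513e-02
5.42306584e-01,7.60114272e-02,2.69565203e-02
5.70063111e-01,7.43757193e-02,2.68909487e-02
5.99240281e-01,7.27608678e-02,2.68132924e-02
6.29910808e-01,7.11664452e-02,2.67229635e-02
6.62151125e-01,6.95921070e-02,2.66195098e-02
6.96041577e-01,6.80375790e-02,2.65025986e-02
7.31666622e-01,6.65026466e-02,2.63720026e-02
7.69115040e-01,6.49871466e-02,2.62275882e-02
8.08480157e-01,6.34909595e-02,2.60693061e-02
8.49860072e-01,6.20140044e-02,2.58971823e-02
8.93357910e-01,6.05562337e-02,2.57113116e-02
9.39082069e-01,5.91176289e-02,2.55118514e-02
9.87146497e-01,5.76981972e-02,2.52990160e-02
1.03767098e+00,5.62979685e-02,2.50730724e-02
1.09078142e+00,5.49169920e-02,2.48343354e-02
1.14661018e+00,5.35553337e-02,2.45831644e-02
1.20529638e+00,5.22130744e-02,2.43199588e-02
1.26698629e+00,5.08903064e-02,2.40451553e-02
1.33183362e+00,4.95871318e-02,2.37592239e-02
1.40000000e+00,4.83036603e-02,2.34626648e-02
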