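# element V (Z=23, A=50.942)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,1.20476615e+02,1.20305742e+02
1.05118235e-02,1.05078447e+02,1.04908054e+02
1.10498434e-02,9.15792990e+01,9.14094084e+01
1.16154003e-02,7.97215473e+01,7.95521815e+01
1.22099038e-02,6.93640916e+01,6.91952737e+01
1.28348354e-02,6.03242547e+01,6.01560087e+01
1.34917525e-02,5.24397688e+01,5.22721196e+01
1.41822921e-02,4.55663234e+01,4.53992967e+01
1.49081752e-02,3.95772040e+01,3.94108264e+01
1.56712107e-02,3.43611990e+01,3.41954980e+01
1.64733001e-02,2.98207499e+01,2.96557538e+01
1.73164423e-02,2.58703142e+01,2.57060523e+01
1.82027386e-02,2.24349206e+01,2.22714230e+01
1.91343975e-02,1.94489169e+01,1.92862146e+01
2.01137410e-02,1.68548093e+01,1.66929342e+01
2.11432096e-02,1.46022863e+01,1.44412711e+01
2.22253688e-02,1.26473440e+01,1.24872222e+01
2.33629154e-02,1.09515144e+01,1.07923205e+01
2.45586844e-02,9.48044817e+00,9.32221719e+00
2.58156556e-02,8.20639723e+00,8.04916515e+00
2.71369616e-02,7.10044386e+00,6.94424734e+00
2.85258951e-02,6.13869943e+00,5.98357580e+00
2.99859175e-02,5.30879200e+00,5.15477923e+00
3.15206672e-02,4.59280035e+00,4.43993698e+00
3.31339691e-02,3.97521541e+00,3.82354052e+00
3.48298436e-02,3.44261866e+00,3.29217177e+00
3.66125169e-02,2.98340298e+00,2.83422399e+00
3.84864316e-02,2.58753045e+00,2.43965956e+00
4.04562577e-02,2.24632226e+00,2.09979989e+00
4.25269041e-02,1.95227647e+00,1.80714318e+00
4.47035311e-02,1.69890998e+00,1.55520633e+00
4.69915629e-02,1.48062153e+00,1.33838801e+00
4.93967017e-02,1.29257290e+00,1.15184982e+00
5.19249410e-02,1.13058606e+00,9.91413410e-01
5.45825816e-02,9.91053946e-01,8.53471300e-01
5.73762465e-02,8.70863240e-01,7.34909623e-01
6.03128978e-02,7.67327482e-01,6.33041242e-01
6.33998537e-02,6.78129147e-01,5.45547824e-01
6.66448073e-02,6.01269513e-01,4.70429708e-01
7.00558453e-02,5.35025272e-01,4.05962515e-01
7.36414682e-02,4.77910994e-01,3.50659608e-01
7.74106118e-02,4.28646649e-01,3.03239621e-01
8.13726689e-02,3.86129528e-01,2.62598380e-01
8.55375135e-02,3.49409963e-01,2.27784622e-01
8.99155246e-02,3.17670334e-01,1.97979018e-01
9.45176126e-02,2.90206937e-01,1.72476034e-01
9.93552463e-02,2.66414307e-01,1.50668269e-01
1.04440482e-01,2.45771685e-01,1.32032931e-01
1.09785991e-01,2.27831325e-01,1.16120147e-01
1.15405096e-01,2.12208401e-01,1.02542888e-01
1.21311800e-01,1.98572294e-01,9.09682616e-02
1.27520824e-01,1.86639073e-01,8.11100071e-02
1.34047639e-01,1.76165006e-01,7.27220197e-02
1.40908513e-01,1.66940962e-01,6.55927662e-02
1.48120542e-01,1.58787586e-01,5.95404716e-02
1.55701700e-01,1.51551136e-01,5.44089697e-02
1.63670879e-01,1.45099893e-01,5.00641286e-02
1.72047939e-01,1.39321068e-01,4.63907708e-02
1.80853757e-01,1.34118138e-01,4.32900203e-02
1.90110278e-01,1.29408551e-01,4.06770192e-02
1.99840569e-01,1.25121744e-01,3.84789603e-02
2.10068880e-01,1.21197444e-01,3.66333952e-02
2.20820699e-01,1.17584197e-01,3.50867772e-02
2.32122822e-01,1.14238114e-01,3.37932077e-02
2.44003413e-01,1.11121776e-01,3.27133580e-02
2.56492082e-01,1.08203308e-01,3.18135415e-02
2.69619950e-01,1.05455574e-01,3.10649156e-02
2.83419733e-01,1.02855487e-01,3.04427959e-02
2.97925822e-01,1.00383417e-01,2.99260662e-02
3.13174366e-01,9.80226872e-02,2.94966715e-02
3.29203366e-01,9.57591326e-02,2.91391820e-02
3.46052769e-01,9.35807318e-02,2.88404194e-02
3.63764564e-01,9.14772861e-02,2.85891348e-02
3.82382889e-01,8.94401469e-02,2.83757330e-02
4.01954145e-01,8.74619828e-02,2.81920362e-02
4.22527103e-01,8.55365807e-02,2.80310805e-02
4.44153034e-01,8.36586770e-02,2.78869425e-02
4.66885831e-01,8.18238136e-02,2.77545900e-02
4.90782146e-01,8.00282153e-02,2.76297554e-02
5.15901531e-01,7.82686865e-02,2.75088262e-02
5.42306584e-01,7.65425231e-02,2.73887527e-02
5.70063111e-01,7.48474385e-02,2.72669687e-02
5.99240281e-01,7.31815005e-02,2.71413241e-02
6.29910808e-01,7.15430786e-02,2.70100272e-02
6.62151125e-01,6.99307990e-02,2.68715965e-02
6.96041577e-01,6.83435072e-02,2.67248187e-02
7.31666622e-01,6.67802358e-02,2.65687139e-02
7.69115040e-01,6.52401780e-02,2.64025050e-02
8.08480157e-01,6.37226645e-02,2.62255928e-02
8.49860072e-01,6.22271445e-02,2.60375338e-02
8.93357910e-01,6.07531690e-02,2.58380217e-02
9.39082069e-01,5.93003769e-02,2.56268716e-02
9.87146497e-01,5.78684831e-02,2.54040057e-02
1.03767098e+00,5.64572675e-02,2.51694418e-02
1.09078142e+00,5.50665666e-02,2.49232825e-02
1.14661018e+00,5.36962647e-02,2.46657059e-02
1.20529638e+00,5.23462878e-02,2.43969574e-02
1.26698629e+00,5.10165962e-02,2.41173424e-02
1.33183362e+00,4.97071798e-02,2.38272192e-02
1.40000000e+00,4.84180521e-02,2.35269929e-02
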