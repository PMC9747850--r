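# element K (Z=19, A=39.098)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,7.75613956e+01,7.73774783e+01
1.05118235e-02,6.73153430e+01,6.71319432e+01
1.10498434e-02,5.83989284e+01,5.82160694e+01
1.16154003e-02,5.06431995e+01,5.04609053e+01
1.22099038e-02,4.39002039e+01,4.37184994e+01
1.28348354e-02,3.80404379e+01,3.78593489e+01
1.34917525e-02,3.29505973e+01,3.27701508e+01
1.41822921e-02,2.85315976e+01,2.83518210e+01
1.49081752e-02,2.46968287e+01,2.45177508e+01
1.56712107e-02,2.13699290e+01,2.11915793e+01
1.64733001e-02,1.84754904e+01,1.82978995e+01
1.73164423e-02,1.59707295e+01,1.57939288e+01
1.82027386e-02,1.38039344e+01,1.36279563e+01
1.91343975e-02,1.19301515e+01,1.17550295e+01
2.01137410e-02,1.03103166e+01,1.01360848e+01
2.11432096e-02,8.91049431e+00,8.73718809e+00
2.22253688e-02,7.70121574e+00,7.52887116e+00
2.33629154e-02,6.65689930e+00,6.48555336e+00
2.45586844e-02,5.75534595e+00,5.58503650e+00
2.58156556e-02,4.97729877e+00,4.80806448e+00
2.71369616e-02,4.30368851e+00,4.13556882e+00
2.85258951e-02,3.71924985e+00,3.55228495e+00
2.99859175e-02,3.21672351e+00,3.05095427e+00
3.15206672e-02,2.78468562e+00,2.62015353e+00
3.31339691e-02,2.41329355e+00,2.25004065e+00
3.48298436e-02,2.09406856e+00,1.93213740e+00
3.66125169e-02,1.81970814e+00,1.65914166e+00
3.84864316e-02,1.58392394e+00,1.42476542e+00
4.04562577e-02,1.38130197e+00,1.22359491e+00
4.25269041e-02,1.20718182e+00,1.05096987e+00
4.47035311e-02,1.05755262e+00,9.02879439e-01
4.69915629e-02,9.28963077e-01,7.75872252e-01
4.93967017e-02,8.18444052e-01,6.66978959e-01
5.19249410e-02,7.23441669e-01,5.73645359e-01
5.45825816e-02,6.41759694e-01,4.93674761e-01
5.73762465e-02,5.71509831e-01,4.25178278e-01
6.03128978e-02,5.11068892e-01,3.66531994e-01
6.33998537e-02,4.59041876e-01,3.16340038e-01
6.66448073e-02,4.14230155e-01,2.73402774e-01
7.00558453e-02,3.75604071e-01,2.36689387e-01
7.36414682e-02,3.42279325e-01,2.05314282e-01
7.74106118e-02,3.13496647e-01,1.78516751e-01
8.13726689e-02,2.88604288e-01,1.55643465e-01
8.55375135e-02,2.67042948e-01,1.36133412e-01
8.99155246e-02,2.48332802e-01,1.19504923e-01
9.45176126e-02,2.32062335e-01,1.05344515e-01
9.93552463e-02,2.17878733e-01,9.32972921e-02
1.04440482e-01,2.05479616e-01,8.30586843e-02
1.09785991e-01,1.94605933e-01,7.43673511e-02
1.15405096e-01,1.85035837e-01,6.69990745e-02
1.21311800e-01,1.76579432e-01,6.07615122e-02
1.27520824e-01,1.69074250e-01,5.54896880e-02
1.34047639e-01,1.62381360e-01,5.10421172e-02
1.40908513e-01,1.56382026e-01,4.72974783e-02
1.48120542e-01,1.50974836e-01,4.41517539e-02
1.55701700e-01,1.46073231e-01,4.15157765e-02
1.63670879e-01,1.41603381e-01,3.93131198e-02
1.72047939e-01,1.37502364e-01,3.74782903e-02
1.80853757e-01,1.33716600e-01,3.59551733e-02
1.90110278e-01,1.30200499e-01,3.46957004e-02
1.99840569e-01,1.26915312e-01,3.36587051e-02
2.10068880e-01,1.23828134e-01,3.28089411e-02
2.20820699e-01,1.20911050e-01,3.21162400e-02
2.32122822e-01,1.18140406e-01,3.15547879e-02
2.44003413e-01,1.15496181e-01,3.11025053e-02
2.56492082e-01,1.12961447e-01,3.07405140e-02
2.69619950e-01,1.10521905e-01,3.04526812e-02
2.83419733e-01,1.08165495e-01,3.02252262e-02
2.97925822e-01,1.05882054e-01,3.00463848e-02
3.13174366e-01,1.03663027e-01,2.99061201e-02
3.29203366e-01,1.01501218e-01,2.97958749e-02
3.46052769e-01,9.93905838e-02,2.97083596e-02
3.63764564e-01,9.73260491e-02,2.96373694e-02
3.82382889e-01,9.53033573e-02,2.95776290e-02
4.01954145e-01,9.33189398e-02,2.95246584e-02
4.22527103e-01,9.13698062e-02,2.94746591e-02
4.44153034e-01,8.94534517e-02,2.94244161e-02
4.66885831e-01,8.75677792e-02,2.93712147e-02
4.90782146e-01,8.57110335e-02,2.93127694e-02
5.15901531e-01,8.38817462e-02,2.92471633e-02
5.42306584e-01,8.20786902e-02,2.91727971e-02
5.70063111e-01,8.03008408e-02,2.90883452e-02
5.99240281e-01,7.85473441e-02,2.89927192e-02
6.29910808e-01,7.68174906e-02,2.88850362e-02
6.62151125e-01,7.51106932e-02,2.87645930e-02
6.96041577e-01,7.34264690e-02,2.86308437e-02
7.31666622e-01,7.17644243e-02,2.84833807e-02
7.69115040e-01,7.01242422e-02,2.83219194e-02
8.08480157e-01,6.85056718e-02,2.81462843e-02
8.49860072e-01,6.69085201e-02,2.79563978e-02
8.93357910e-01,6.53326439e-02,2.77522705e-02
9.39082069e-01,6.37779441e-02,2.75339925e-02
9.87146497e-01,6.22443595e-02,2.73017263e-02
1.03767098e+00,6.07318627e-02,2.70557001e-02
1.09078142e+00,5.92404552e-02,2.67962022e-02
1.14661018e+00,5.77701638e-02,2.65235751e-02
1.20529638e+00,5.63210367e-02,2.62382114e-02
1.26698629e+00,5.48931403e-02,2.59405486e-02
1.33183362e+00,5.34865559e-02,2.56310646e-02
1.40000000e+00,5.21013767e-02,2.53102739e-02
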