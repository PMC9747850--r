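# element C (Z=6, A=12.011)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,2.15770061e+00,1.96864236e+00
1.05118235e-02,1.86500427e+00,1.67647804e+00
1.10498434e-02,1.61558402e+00,1.42761364e+00
1.16154003e-02,1.40305743e+00,1.21566762e+00
1.22099038e-02,1.22197834e+00,1.03519476e+00
1.28348354e-02,1.06770024e+00,8.81549435e-01
1.34917525e-02,9.36259310e-01,7.50768799e-01
1.41822921e-02,8.24274627e-01,6.39472874e-01
1.49081752e-02,7.28862812e-01,5.44779246e-01
1.56712107e-02,6.47565147e-01,4.64230167e-01
1.64733001e-02,5.78285301e-01,3.95730282e-01
1.73164423e-02,5.19236157e-01,3.37493450e-01
1.82027386e-02,4.68894398e-01,2.87997329e-01
1.91343975e-02,4.25961728e-01,2.45944593e-01
2.01137410e-02,3.89331778e-01,2.10229833e-01
2.11432096e-02,3.58061846e-01,1.79911291e-01
2.22253688e-02,3.31348783e-01,1.54186748e-01
2.33629154e-02,3.08508418e-01,1.32372937e-01
2.45586844e-02,2.88958003e-01,1.13887984e-01
2.58156556e-02,2.72201231e-01,9.82364242e-02
2.71369616e-02,2.57767803e-01,8.49487594e-02
2.85258951e-02,2.45283760e-01,7.36517863e-02
2.99859175e-02,2.34548614e-01,6.41457167e-02
3.15206672e-02,2.25289201e-01,5.61580304e-02
3.31339691e-02,2.17274135e-01,4.94579173e-02
3.48298436e-02,2.10307408e-01,4.38498712e-02
3.66125169e-02,2.04222973e-01,3.91682668e-02
3.84864316e-02,1.98880162e-01,3.52727699e-02
4.04562577e-02,1.94159807e-01,3.20444515e-02
4.25269041e-02,1.89960957e-01,2.93824986e-02
4.47035311e-02,1.86198103e-01,2.72014295e-02
4.69915629e-02,1.82798825e-01,2.54287366e-02
4.93967017e-02,1.79701804e-01,2.40028907e-02
5.19249410e-02,1.76855135e-01,2.28716515e-02
5.45825816e-02,1.74214906e-01,2.19906373e-02
5.73762465e-02,1.71743993e-01,2.13221153e-02
6.03128978e-02,1.69411034e-01,2.08339759e-02
6.33998537e-02,1.67189570e-01,2.04988670e-02
6.66448073e-02,1.65057310e-01,2.02934593e-02
7.00558453e-02,1.62995516e-01,2.01978270e-02
7.36414682e-02,1.60988473e-01,2.01949228e-02
7.74106118e-02,1.59023049e-01,2.02701343e-02
8.13726689e-02,1.57088314e-01,2.04109103e-02
8.55375135e-02,1.55175222e-01,2.06064443e-02
8.99155246e-02,1.53276342e-01,2.08474079e-02
9.45176126e-02,1.51385619e-01,2.11257266e-02
9.93552463e-02,1.49498186e-01,2.14343899e-02
1.04440482e-01,1.47610190e-01,2.17672928e-02
1.09785991e-01,1.45718646e-01,2.21191022e-02
1.15405096e-01,1.43821323e-01,2.24851443e-02
1.21311800e-01,1.41916625e-01,2.28613108e-02
1.27520824e-01,1.40003509e-01,2.32439803e-02
1.34047639e-01,1.38081399e-01,2.36299521e-02
1.40908513e-01,1.36150119e-01,2.40163912e-02
1.48120542e-01,1.34209831e-01,2.44007820e-02
1.55701700e-01,1.32260980e-01,2.47808895e-02
1.63670879e-01,1.30304250e-01,2.51547266e-02
1.72047939e-01,1.28340518e-01,2.55205268e-02
1.80853757e-01,1.26370818e-01,2.58767206e-02
1.90110278e-01,1.24396307e-01,2.62219153e-02
1.99840569e-01,1.22418236e-01,2.65548780e-02
2.10068880e-01,1.20437922e-01,2.68745203e-02
2.20820699e-01,1.18456727e-01,2.71798849e-02
2.32122822e-01,1.16476032e-01,2.74701336e-02
2.44003413e-01,1.14497222e-01,2.77445364e-02
2.56492082e-01,1.12521671e-01,2.80024620e-02
2.69619950e-01,1.10550723e-01,2.82433682e-02
2.83419733e-01,1.08585684e-01,2.84667937e-02
2.97925822e-01,1.06627812e-01,2.86723502e-02
3.13174366e-01,1.04678308e-01,2.88597154e-02
3.29203366e-01,1.02738309e-01,2.90286259e-02
3.46052769e-01,1.00808884e-01,2.91788715e-02
3.63764564e-01,9.88910335e-02,2.93102896e-02
3.82382889e-01,9.69856833e-02,2.94227600e-02
4.01954145e-01,9.50936886e-02,2.95162009e-02
4.22527103e-01,9.32158328e-02,2.95905649e-02
4.44153034e-01,9.13528303e-02,2.96458363e-02
4.66885831e-01,8.95053288e-02,2.96820279e-02
4.90782146e-01,8.76739134e-02,2.96991798e-02
5.15901531e-01,8.58591109e-02,2.96973576e-02
5.42306584e-01,8.40613939e-02,2.96766515e-02
5.70063111e-01,8.22811863e-02,2.96371762e-02
5.99240281e-01,8.05188684e-02,2.95790704e-02
6.29910808e-01,7.87747815e-02,2.95024976e-02
6.62151125e-01,7.70492335e-02,2.94076463e-02
6.96041577e-01,7.53425037e-02,2.92947309e-02
7.31666622e-01,7.36548471e-02,2.91639924e-02
7.69115040e-01,7.19864993e-02,2.90156993e-02
8.08480157e-01,7.03376798e-02,2.88501486e-02
8.49860072e-01,6.87085958e-02,2.86676663e-02
8.93357910e-01,6.70994452e-02,2.84686083e-02
9.39082069e-01,6.55104191e-02,2.82533603e-02
9.87146497e-01,6.39417039e-02,2.80223386e-02
1.03767098e+00,6.23934829e-02,2.77759892e-02
1.09078142e+00,6.08659375e-02,2.75147881e-02
1.14661018e+00,5.93592476e-02,2.72392403e-02
1.20529638e+00,5.78735925e-02,2.69498786e-02
1.26698629e+00,5.64091503e-02,2.66472627e-02
1.33183362e+00,5.49660979e-02,2.63319773e-02
1.40000000e+00,5.35446102e-02,2.60046304e-02
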