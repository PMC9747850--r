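# element Na (Z=11, A=22.990)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,1.47863666e+01,1.46052837e+01
1.05118235e-02,1.27215097e+01,1.25409364e+01
1.10498434e-02,1.09452905e+01,1.07652497e+01
1.16154003e-02,9.41781290e+00,9.23832814e+00
1.22099038e-02,8.10462926e+00,7.92572514e+00
1.28348354e-02,6.97600583e+00,6.79770779e+00
1.34917525e-02,6.00628533e+00,5.82861973e+00
1.41822921e-02,5.17333454e+00,4.99632866e+00
1.49081752e-02,4.45806384e+00,4.28174584e+00
1.56712107e-02,3.84402337e+00,3.66842238e+00
1.64733001e-02,3.31703105e+00,3.14217711e+00
1.73164423e-02,2.86486801e+00,2.69079212e+00
1.82027386e-02,2.47701011e+00,2.30374419e+00
1.91343975e-02,2.14439562e+00,1.97197251e+00
2.01137410e-02,1.85922445e+00,1.68767792e+00
2.11432096e-02,1.61478455e+00,1.44414928e+00
2.22253688e-02,1.40530194e+00,1.23561348e+00
2.33629154e-02,1.22576425e+00,1.05705904e+00
2.45586844e-02,1.07196129e+00,9.04276602e-01
2.58156556e-02,9.40281561e-01,7.73655461e-01
2.71369616e-02,8.27546885e-01,6.62018214e-01
2.85258951e-02,7.31024665e-01,5.66632987e-01
2.99859175e-02,6.48371536e-01,4.85157087e-01
3.15206672e-02,5.77585756e-01,4.15589385e-01
3.31339691e-02,5.16951197e-01,3.56214308e-01
3.48298436e-02,4.64996959e-01,3.05561435e-01
3.66125169e-02,4.20462635e-01,2.62370763e-01
3.84864316e-02,3.82268462e-01,2.25562849e-01
4.04562577e-02,3.49489661e-01,1.94213144e-01
4.25269041e-02,3.21334403e-01,1.67529948e-01
4.47035311e-02,2.97124865e-01,1.44835467e-01
4.69915629e-02,2.76280982e-01,1.25549552e-01
4.93967017e-02,2.58306483e-01,1.09175730e-01
5.19249410e-02,2.42776911e-01,9.52892220e-02
5.45825816e-02,2.29329343e-01,8.35266566e-02
5.73762465e-02,2.17653575e-01,7.35772456e-02
6.03128978e-02,2.07484551e-01,6.51752174e-02
6.33998537e-02,1.98595883e-01,5.80933282e-02
6.66448073e-02,1.90794287e-01,5.21373003e-02
7.00558453e-02,1.83914823e-01,4.71410559e-02
7.36414682e-02,1.77816808e-01,4.29626343e-02
7.74106118e-02,1.72380317e-01,3.94806952e-02
8.13726689e-02,1.67503191e-01,3.65915252e-02
8.55375135e-02,1.63098469e-01,3.42064755e-02
8.99155246e-02,1.59092188e-01,3.22497698e-02
9.45176126e-02,1.55421508e-01,3.06566300e-02
9.93552463e-02,1.52033097e-01,2.93716726e-02
1.04440482e-01,1.48881752e-01,2.83475393e-02
1.09785991e-01,1.45929223e-01,2.75437263e-02
1.15405096e-01,1.43143196e-01,2.69255850e-02
1.21311800e-01,1.40496433e-01,2.64634684e-02
1.27520824e-01,1.37966030e-01,2.61320029e-02
1.34047639e-01,1.35532779e-01,2.59094668e-02
1.40908513e-01,1.33180626e-01,2.57772601e-02
1.48120542e-01,1.30896206e-01,2.57194527e-02
1.55701700e-01,1.28668441e-01,2.57223983e-02
1.63670879e-01,1.26488197e-01,2.57744063e-02
1.72047939e-01,1.24347990e-01,2.58654607e-02
1.80853757e-01,1.22241734e-01,2.59869812e-02
1.90110278e-01,1.20164523e-01,2.61316187e-02
1.99840569e-01,1.18112442e-01,2.62930812e-02
2.10068880e-01,1.16082413e-01,2.64659843e-02
2.20820699e-01,1.14072052e-01,2.66457239e-02
2.32122822e-01,1.12079551e-01,2.68283670e-02
2.44003413e-01,1.10103581e-01,2.70105576e-02
2.56492082e-01,1.08143202e-01,2.71894366e-02
2.69619950e-01,1.06197791e-01,2.73625725e-02
2.83419733e-01,1.04266976e-01,2.75279020e-02
2.97925822e-01,1.02350589e-01,2.76836785e-02
3.13174366e-01,1.00448613e-01,2.78284283e-02
3.29203366e-01,9.85611515e-02,2.79609119e-02
3.46052769e-01,9.66883922e-02,2.80800919e-02
3.63764564e-01,9.48305843e-02,2.81851046e-02
3.82382889e-01,9.29880163e-02,2.82752355e-02
4.01954145e-01,9.11609999e-02,2.83498990e-02
4.22527103e-01,8.93498562e-02,2.84086207e-02
4.44153034e-01,8.75549064e-02,2.84510224e-02
4.66885831e-01,8.57764640e-02,2.84768096e-02
4.90782146e-01,8.40148302e-02,2.84857612e-02
5.15901531e-01,8.22702900e-02,2.84777207e-02
5.42306584e-01,8.05431111e-02,2.84525895e-02
5.70063111e-01,7.88335431e-02,2.84103209e-02
5.99240281e-01,7.71418180e-02,2.83509158e-02
6.29910808e-01,7.54681513e-02,2.82744191e-02
6.62151125e-01,7.38127439e-02,2.81809174e-02
6.96041577e-01,7.21757838e-02,2.80705367e-02
7.31666622e-01,7.05574485e-02,2.79434408e-02
7.69115040e-01,6.89579070e-02,2.77998305e-02
8.08480157e-01,6.73773222e-02,2.76399428e-02
8.49860072e-01,6.58158524e-02,2.74640498e-02
8.93357910e-01,6.42736534e-02,2.72724586e-02
9.39082069e-01,6.27508797e-02,2.70655103e-02
9.87146497e-01,6.12476861e-02,2.68435795e-02
1.03767098e+00,5.97642280e-02,2.66070735e-02
1.09078142e+00,5.83006619e-02,2.63564311e-02
1.14661018e+00,5.68571463e-02,2.60921218e-02
1.20529638e+00,5.54338406e-02,2.58146439e-02
1.26698629e+00,5.40309055e-02,2.55245234e-02
1.33183362e+00,5.26485019e-02,2.52223120e-02
1.40000000e+00,5.12867902e-02,2.49085847e-02
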