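# element Cr (Z=24, A=51.996)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,1.37378501e+02,1.37203812e+02
1.05118235e-02,1.19952588e+02,1.19778391e+02
1.10498434e-02,1.04674402e+02,1.04500719e+02
1.16154003e-02,9.12868552e+01,9.11137081e+01
1.22099038e-02,7.95399999e+01,7.93674130e+01
1.28348354e-02,6.92341956e+01,6.90621933e+01
1.34917525e-02,6.02338873e+01,6.00624951e+01
1.41822921e-02,5.23796181e+01,5.22088623e+01
1.49081752e-02,4.55300363e+01,4.53599442e+01
1.56712107e-02,3.95595542e+01,3.93901538e+01
1.64733001e-02,3.43579066e+01,3.41892268e+01
1.73164423e-02,2.98283275e+01,2.96603983e+01
1.82027386e-02,2.58859387e+01,2.57187909e+01
1.91343975e-02,2.24563257e+01,2.22899909e+01
2.01137410e-02,1.94742753e+01,1.93087862e+01
2.11432096e-02,1.68826799e+01,1.67180698e+01
2.22253688e-02,1.46315409e+01,1.44678443e+01
2.33629154e-02,1.26771100e+01,1.25143618e+01
2.45586844e-02,1.09811274e+01,1.08193637e+01
2.58156556e-02,9.51015097e+00,9.34940851e+00
2.71369616e-02,8.23085637e+00,8.07117258e+00
2.85258951e-02,7.11688501e+00,6.95829807e+00
2.99859175e-02,6.15515117e+00,5.99769988e+00
3.15206672e-02,5.32501902e+00,5.16874281e+00
3.31339691e-02,4.60862382e+00,4.45356261e+00
3.48298436e-02,3.99050298e+00,3.83669719e+00
3.66125169e-02,3.45727604e+00,3.30476646e+00
3.84864316e-02,2.99736676e+00,2.84619449e+00
4.04562577e-02,2.60076208e+00,2.45096844e+00
4.25269041e-02,2.25880296e+00,2.11042941e+00
4.47035311e-02,1.96400303e+00,1.81709103e+00
4.69915629e-02,1.70989118e+00,1.56448214e+00
4.93967017e-02,1.49087527e+00,1.34701039e+00
5.19249410e-02,1.30212381e+00,1.15984397e+00
5.45825816e-02,1.13946351e+00,9.98809175e-01
5.73762465e-02,9.99290504e-01,8.60301569e-01
6.03128978e-02,8.78493398e-01,7.41209065e-01
6.33998537e-02,7.74386648e-01,6.38845296e-01
6.66448073e-02,6.84652866e-01,5.50891914e-01
7.00558453e-02,6.07292864e-01,4.75348634e-01
7.36414682e-02,5.40582416e-01,4.10489998e-01
7.74106118e-02,4.83034844e-01,3.54827962e-01
8.13726689e-02,4.33368641e-01,3.07079519e-01
8.55375135e-02,3.90479469e-01,2.66138705e-01
8.99155246e-02,3.53415947e-01,2.31052386e-01
9.45176126e-02,3.21358704e-01,2.00999325e-01
9.93552463e-02,2.93602289e-01,1.75272090e-01
1.04440482e-01,2.69539523e-01,1.53261422e-01
1.09785991e-01,2.48647984e-01,1.34442728e-01
1.15405096e-01,2.30478337e-01,1.18364418e-01
1.21311800e-01,2.14644246e-01,1.04637832e-01
1.27520824e-01,2.00813668e-01,9.29285460e-02
1.34047639e-01,1.88701338e-01,8.29488698e-02
1.40908513e-01,1.78062280e-01,7.44513707e-02
1.48120542e-01,1.68686210e-01,6.72232909e-02
1.55701700e-01,1.60392706e-01,6.10817303e-02
1.63670879e-01,1.53027040e-01,5.58694946e-02
1.72047939e-01,1.46456586e-01,5.14515154e-02
1.80853757e-01,1.40567725e-01,4.77117663e-02
1.90110278e-01,1.35263167e-01,4.45506037e-02
1.99840569e-01,1.30459660e-01,4.18824781e-02
2.10068880e-01,1.26085998e-01,3.96339614e-02
2.20820699e-01,1.22081317e-01,3.77420485e-02
2.32122822e-01,1.18393625e-01,3.61526952e-02
2.44003413e-01,1.14978534e-01,3.48195593e-02
2.56492082e-01,1.11798172e-01,3.37029170e-02
2.69619950e-01,1.08820245e-01,3.27687304e-02
2.83419733e-01,1.06017232e-01,3.19878454e-02
2.97925822e-01,1.03365692e-01,3.13353011e-02
3.13174366e-01,1.00845673e-01,3.07897368e-02
3.29203366e-01,9.84401973e-02,3.03328810e-02
3.46052769e-01,9.61348258e-02,2.99491127e-02
3.63764564e-01,9.39172854e-02,2.96250848e-02
3.82382889e-01,9.17771461e-02,2.93494000e-02
4.01954145e-01,8.97055480e-02,2.91123328e-02
4.22527103e-01,8.76949665e-02,2.89055909e-02
4.44153034e-01,8.57390127e-02,2.87221110e-02
4.66885831e-01,8.38322636e-02,2.85558833e-02
4.90782146e-01,8.19701165e-02,2.84018016e-02
5.15901531e-01,8.01486667e-02,2.82555350e-02
5.42306584e-01,7.83646021e-02,2.81134182e-02
5.70063111e-01,7.66151154e-02,2.79723578e-02
5.99240281e-01,7.48978283e-02,2.78297528e-02
6.29910808e-01,7.32107282e-02,2.76834260e-02
6.62151125e-01,7.15521145e-02,2.75315665e-02
6.96041577e-01,6.99205528e-02,2.73726800e-02
7.31666622e-01,6.83148365e-02,2.72055469e-02
7.69115040e-01,6.67339543e-02,2.70291863e-02
8.08480157e-01,6.51770623e-02,2.68428260e-02
8.49860072e-01,6.36434605e-02,2.66458758e-02
8.93357910e-01,6.21325729e-02,2.64379055e-02
9.39082069e-01,6.06439301e-02,2.62186257e-02
9.87146497e-01,5.91771548e-02,2.59878712e-02
1.03767098e+00,5.77319487e-02,2.57455869e-02
1.09078142e+00,5.63080817e-02,2.54918147e-02
1.14661018e+00,5.49053822e-02,2.52266833e-02
1.20529638e+00,5.35237284e-02,2.49503976e-02
1.26698629e+00,5.21630407e-02,2.46632306e-02
1.33183362e+00,5.08232751e-02,2.43655151e-02
1.40000000e+00,4.95044170e-02,2.40576368e-02
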