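# element N (Z=7, A=14.007)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,3.57581223e+00,3.38667525e+00
1.05118235e-02,3.07759584e+00,2.88899109e+00
1.10498434e-02,2.65220503e+00,2.46415637e+00
1.16154003e-02,2.28904407e+00,2.10157622e+00
1.22099038e-02,1.97904517e+00,1.79218379e+00
1.28348354e-02,1.71445729e+00,1.52822896e+00
1.34917525e-02,1.48865682e+00,1.30308906e+00
1.41822921e-02,1.29597506e+00,1.11109634e+00
1.49081752e-02,1.13156625e+00,9.47406024e-01
1.56712107e-02,9.91288808e-01,8.07877477e-01
1.64733001e-02,8.71603562e-01,6.88972516e-01
1.73164423e-02,7.69486669e-01,5.87668274e-01
1.82027386e-02,6.82355000e-01,5.01382596e-01
1.91343975e-02,6.08002274e-01,4.27910169e-01
2.01137410e-02,5.44544393e-01,3.65367859e-01
2.11432096e-02,4.90372662e-01,3.12147915e-01
2.22253688e-02,4.44113752e-01,2.66877937e-01
2.33629154e-02,4.04595458e-01,2.28386624e-01
2.45586844e-02,3.70817406e-01,1.95674478e-01
2.58156556e-02,3.41926000e-01,1.67888745e-01
2.71369616e-02,3.17121649e-01,1.44230634e-01
2.85258951e-02,2.95761736e-01,1.24058284e-01
2.99859175e-02,2.77475056e-01,1.07001193e-01
3.15206672e-02,2.61791546e-01,9.25899393e-02
3.31339691e-02,2.48312082e-01,8.04259758e-02
3.48298436e-02,2.36697779e-01,7.01709196e-02
3.66125169e-02,2.26660905e-01,6.15374603e-02
3.84864316e-02,2.17957167e-01,5.42816390e-02
4.04562577e-02,2.10379162e-01,4.81962928e-02
4.25269041e-02,2.03750821e-01,4.31054883e-02
4.47035311e-02,1.97922685e-01,3.88597957e-02
4.69915629e-02,1.92767903e-01,3.53322762e-02
4.93967017e-02,1.88178830e-01,3.24150750e-02
5.19249410e-02,1.84064140e-01,3.00165295e-02
5.45825816e-02,1.80346378e-01,2.80587145e-02
5.73762465e-02,1.76959880e-01,2.64753577e-02
6.03128978e-02,1.73849006e-01,2.52100717e-02
6.33998537e-02,1.70966646e-01,2.42148528e-02
6.66448073e-02,1.68272947e-01,2.34488078e-02
7.00558453e-02,1.65734232e-01,2.28770737e-02
7.36414682e-02,1.63322087e-01,2.24699016e-02
7.74106118e-02,1.61012579e-01,2.22018798e-02
8.13726689e-02,1.58785600e-01,2.20512759e-02
8.55375135e-02,1.56624299e-01,2.19994786e-02
8.99155246e-02,1.54514611e-01,2.20305258e-02
9.45176126e-02,1.52444845e-01,2.21307046e-02
9.93552463e-02,1.50405343e-01,2.22882134e-02
1.04440482e-01,1.48388181e-01,2.24928761e-02
1.09785991e-01,1.46386918e-01,2.27359000e-02
1.15405096e-01,1.44396383e-01,2.30096728e-02
1.21311800e-01,1.42412486e-01,2.33075898e-02
1.27520824e-01,1.40432063e-01,2.36239091e-02
1.34047639e-01,1.38452741e-01,2.39536292e-02
1.40908513e-01,1.36472813e-01,2.42923857e-02
1.48120542e-01,1.34491144e-01,2.46363643e-02
1.55701700e-01,1.32507079e-01,2.49822273e-02
1.63670879e-01,1.30520366e-01,2.53270516e-02
1.72047939e-01,1.28531088e-01,2.56682760e-02
1.80853757e-01,1.26539605e-01,2.60036563e-02
1.90110278e-01,1.24546505e-01,2.63312276e-02
1.99840569e-01,1.22552552e-01,2.66492709e-02
2.10068880e-01,1.20558653e-01,2.69562856e-02
2.20820699e-01,1.18565820e-01,2.72509645e-02
2.32122822e-01,1.16575138e-01,2.75321727e-02
2.44003413e-01,1.14587743e-01,2.77989285e-02
2.56492082e-01,1.12604794e-01,2.80503869e-02
2.69619950e-01,1.10627457e-01,2.82858247e-02
2.83419733e-01,1.08656883e-01,2.85046269e-02
2.97925822e-01,1.06694202e-01,2.87062750e-02
3.13174366e-01,1.04740505e-01,2.88903363e-02
3.29203366e-01,1.02796834e-01,2.90564538e-02
3.46052769e-01,1.00864182e-01,2.92043380e-02
3.63764564e-01,9.89434802e-02,2.93337589e-02
3.82382889e-01,9.70355998e-02,2.94445394e-02
4.01954145e-01,9.51413473e-02,2.95365493e-02
4.22527103e-01,9.32614658e-02,2.96097006e-02
4.44153034e-01,9.13966349e-02,2.96639425e-02
4.66885831e-01,8.95474736e-02,2.96992588e-02
4.90782146e-01,8.77145423e-02,2.97156647e-02
5.15901531e-01,8.58983468e-02,2.97132045e-02
5.42306584e-01,8.40993423e-02,2.96919510e-02
5.70063111e-01,8.23179377e-02,2.96520035e-02
5.99240281e-01,8.05545005e-02,2.95934882e-02
6.29910808e-01,7.88093615e-02,2.95165578e-02
6.62151125e-01,7.70828195e-02,2.94213916e-02
6.96041577e-01,7.53751460e-02,2.93081963e-02
7.31666622e-01,7.36865899e-02,2.91772066e-02
7.69115040e-01,7.20173810e-02,2.90286854e-02
8.08480157e-01,7.03677343e-02,2.88629253e-02
8.49860072e-01,6.87378531e-02,2.86802483e-02
8.93357910e-01,6.71279321e-02,2.84810071e-02
9.39082069e-01,6.55381596e-02,2.82655848e-02
9.87146497e-01,6.39687195e-02,2.80343953e-02
1.03767098e+00,6.24197934e-02,2.77878829e-02
1.09078142e+00,6.08915607e-02,2.75265221e-02
1.14661018e+00,5.93842003e-02,2.72508164e-02
1.20529638e+00,5.78978901e-02,2.69612979e-02
1.26698629e+00,5.64328074e-02,2.66585253e-02
1.33183362e+00,5.49891281e-02,2.63430827e-02
1.40000000e+00,5.35670266e-02,2.60155776e-02
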