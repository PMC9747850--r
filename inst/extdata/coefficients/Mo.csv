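# element Mo (Z=42, A=95.950)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,8.22206681e+01,8.20550042e+01
1.05118235e-02,7.16406742e+01,7.14754765e+01
1.10498434e-02,6.24056724e+01,6.22409618e+01
1.16154003e-02,5.43337352e+01,5.41695333e+01
1.22099038e-02,4.72931817e+01,4.71295110e+01
1.28348354e-02,4.11512523e+01,4.09881361e+01
1.34917525e-02,3.58003537e+01,3.56378161e+01
1.41822921e-02,3.11436889e+01,3.09817548e+01
1.49081752e-02,2.70916259e+01,2.69303211e+01
1.56712107e-02,2.35660490e+01,2.34054002e+01
1.64733001e-02,2.04988175e+01,2.03388521e+01
1.73164423e-02,1.78307120e+01,1.76714584e+01
1.82027386e-02,1.55100694e+01,1.53515568e+01
1.91343975e-02,1.34918689e+01,1.33341274e+01
1.99975000e-02,1.19283105e+01,1.17712762e+01
2.00015000e-02,8.11774895e+01,8.10204584e+01
2.01137410e-02,7.98843958e+01,7.97274562e+01
2.11432096e-02,6.94817406e+01,6.93256347e+01
2.22253688e-02,6.10173448e+01,6.08621051e+01
2.33629154e-02,5.35464065e+01,5.33920663e+01
2.45586844e-02,4.69572471e+01,4.68038405e+01
2.58156556e-02,4.11501633e+01,4.09977252e+01
2.71369616e-02,3.60272666e+01,3.58758324e+01
2.85258951e-02,3.15091607e+01,3.13587667e+01
2.99859175e-02,2.75454313e+01,2.73961143e+01
3.15206672e-02,2.40698499e+01,2.39216473e+01
3.31339691e-02,2.10238831e+01,2.08768327e+01
3.48298436e-02,1.83558229e+01,1.82099630e+01
3.66125169e-02,1.60200127e+01,1.58753821e+01
3.84864316e-02,1.39761588e+01,1.38327965e+01
4.04562577e-02,1.21865820e+01,1.20445270e+01
4.25269041e-02,1.06170603e+01,1.04763520e+01
4.47035311e-02,9.24793742e+00,9.10861524e+00
4.69915629e-02,8.05412379e+00,7.91622692e+00
4.93967017e-02,7.01360460e+00,6.87717211e+00
5.19249410e-02,6.10707110e+00,5.97214177e+00
5.45825816e-02,5.31759511e+00,5.18420730e+00
5.73762465e-02,4.63034179e+00,4.49853335e+00
6.03128978e-02,4.03231644e+00,3.90212454e+00
6.33998537e-02,3.51214114e+00,3.38360217e+00
6.66448073e-02,3.05985800e+00,2.93300745e+00
7.00558453e-02,2.66675576e+00,2.54162807e+00
7.36414682e-02,2.32521717e+00,2.20184562e+00
7.74106118e-02,2.02858458e+00,1.90700117e+00
8.13726689e-02,1.77091949e+00,1.65115476e+00
8.55375135e-02,1.54742330e+00,1.42950627e+00
8.99155246e-02,1.35392211e+00,1.23788013e+00
9.45176126e-02,1.18637669e+00,1.07223536e+00
9.93552463e-02,1.04128926e+00,9.29072277e-01
1.04440482e-01,9.15631167e-01,8.05360263e-01
1.09785991e-01,8.06780279e-01,6.98475132e-01
1.15405096e-01,7.12466690e-01,6.06144836e-01
1.21311800e-01,6.30725625e-01,5.26402398e-01
1.27520824e-01,5.59856640e-01,4.57545114e-01
1.34047639e-01,4.98388243e-01,3.98099193e-01
1.40908513e-01,4.45047240e-01,3.46789111e-01
1.48120542e-01,3.98732158e-01,3.02511049e-01
1.55701700e-01,3.58490225e-01,2.64309885e-01
1.63670879e-01,3.23497408e-01,2.31359248e-01
1.72047939e-01,2.93041132e-01,2.02944243e-01
1.80853757e-01,2.66505291e-01,1.78446487e-01
1.90110278e-01,2.43357279e-01,1.57331138e-01
1.99840569e-01,2.23136745e-01,1.39135666e-01
2.10068880e-01,2.05445854e-01,1.23460130e-01
2.20820699e-01,1.89940855e-01,1.09958749e-01
2.32122822e-01,1.76324778e-01,9.83326059e-02
2.44003413e-01,1.64341112e-01,8.83233360e-02
2.56492082e-01,1.53768325e-01,7.97076529e-02
2.69619950e-01,1.44415131e-01,7.22926150e-02
2.83419733e-01,1.36116382e-01,6.59115262e-02
2.97925822e-01,1.28729521e-01,6.04203876e-02
3.13174366e-01,1.22131511e-01,5.56948264e-02
3.29203366e-01,1.16216173e-01,5.16274388e-02
3.46052769e-01,1.10891895e-01,4.81254897e-02
3.63764564e-01,1.06079640e-01,4.51089238e-02
3.82382889e-01,1.01711228e-01,4.25086441e-02
4.01954145e-01,9.77278526e-02,4.02650237e-02
4.22527103e-01,9.40787978e-02,3.83266181e-02
4.44153034e-01,9.07203288e-02,3.66490528e-02
4.66885831e-01,8.76147352e-02,3.51940613e-02
4.90782146e-01,8.47295044e-02,3.39286532e-02
5.15901531e-01,8.20366083e-02,3.28243964e-02
5.42306584e-01,7.95118875e-02,3.18567965e-02
5.70063111e-01,7.71345205e-02,3.10047608e-02
5.99240281e-01,7.48865649e-02,3.02501355e-02
6.29910808e-01,7.27525627e-02,2.95773068e-02
6.62151125e-01,7.07191995e-02,2.89728554e-02
6.96041577e-01,6.87750104e-02,2.84252596e-02
7.31666622e-01,6.69101268e-02,2.79246385e-02
7.69115040e-01,6.51160576e-02,2.74625302e-02
8.08480157e-01,6.33855013e-02,2.70317007e-02
8.49860072e-01,6.17121828e-02,2.66259793e-02
8.93357910e-01,6.00907136e-02,2.62401156e-02
9.39082069e-01,5.85164702e-02,2.58696570e-02
9.87146497e-01,5.69854899e-02,2.55108418e-02
1.03767098e+00,5.54943801e-02,2.51605081e-02
1.09078142e+00,5.40402405e-02,2.48160135e-02
1.14661018e+00,5.26205947e-02,2.44751664e-02
1.20529638e+00,5.12333325e-02,2.41361664e-02
1.26698629e+00,4.98766583e-02,2.37975524e-02
1.33183362e+00,4.85490475e-02,2.34581569e-02
1.40000000e+00,4.72492077e-02,2.31170673e-02
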