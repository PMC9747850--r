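# element Zn (Z=30, A=65.380)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,2.34042873e+02,2.33869213e+02
1.05118235e-02,2.04836986e+02,2.04663815e+02
1.10498434e-02,1.80035850e+02,1.79863189e+02
1.16154003e-02,1.58107022e+02,1.57934894e+02
1.22099038e-02,1.38734289e+02,1.38562718e+02
1.28348354e-02,1.21585251e+02,1.21414262e+02
1.34917525e-02,1.06429867e+02,1.06259484e+02
1.41822921e-02,9.31069716e+01,9.29372214e+01
1.49081752e-02,8.14024677e+01,8.12333772e+01
1.56712107e-02,7.11263616e+01,7.09579587e+01
1.64733001e-02,6.21101554e+01,6.19424689e+01
1.73164423e-02,5.42045090e+01,5.40375687e+01
1.82027386e-02,4.72771464e+01,4.71109829e+01
1.91343975e-02,4.12109812e+01,4.10456259e+01
2.01137410e-02,3.58911308e+01,3.57266161e+01
2.11432096e-02,3.12418334e+01,3.10781926e+01
2.22253688e-02,2.71833581e+01,2.70206254e+01
2.33629154e-02,2.36424422e+01,2.34806524e+01
2.45586844e-02,2.05548576e+01,2.03940465e+01
2.58156556e-02,1.78639326e+01,1.77041367e+01
2.71369616e-02,1.55178817e+01,1.53591382e+01
2.85258951e-02,1.34728285e+01,1.33151755e+01
2.99859175e-02,1.16951288e+01,1.15386047e+01
3.15206672e-02,1.01504563e+01,9.99510035e+00
3.31339691e-02,8.80880726e+00,8.65465916e+00
3.48298436e-02,7.64396674e+00,7.49106666e+00
3.66125169e-02,6.63303954e+00,6.48142803e+00
3.84864316e-02,5.75603807e+00,5.60575600e+00
4.04562577e-02,4.99552033e+00,4.84660877e+00
4.25269041e-02,4.33454483e+00,4.18704499e+00
4.47035311e-02,3.75935358e+00,3.61330670e+00
4.69915629e-02,3.26235759e+00,3.11780481e+00
4.93967017e-02,2.83299387e+00,2.68997616e+00
5.19249410e-02,2.46211298e+00,2.32067098e+00
5.45825816e-02,2.14179151e+00,2.00196544e+00
5.73762465e-02,1.86516934e+00,1.72699886e+00
6.03128978e-02,1.62630816e+00,1.48983225e+00
6.33998537e-02,1.42006879e+00,1.28532560e+00
6.66448073e-02,1.24200463e+00,1.10903135e+00
7.00558453e-02,1.08826918e+00,9.57101919e-01
7.36414682e-02,9.55535810e-01,8.26209461e-01
7.74106118e-02,8.40928216e-01,7.13476300e-01
8.13726689e-02,7.41960011e-01,6.16414562e-01
8.55375135e-02,6.56482404e-01,5.32873839e-01
8.99155246e-02,5.82638824e-01,4.60995820e-01
9.45176126e-02,5.18825587e-01,3.99174962e-01
9.93552463e-02,4.63657806e-01,3.46024412e-01
1.04440482e-01,4.15939860e-01,3.00346481e-01
1.09785991e-01,3.74639812e-01,2.61107071e-01
1.15405096e-01,3.38867246e-01,2.27413527e-01
1.21311800e-01,3.07854084e-01,1.98495459e-01
1.27520824e-01,2.80937970e-01,1.73688146e-01
1.34047639e-01,2.57547900e-01,1.52418171e-01
1.40908513e-01,2.37191772e-01,1.34190991e-01
1.48120542e-01,2.19445624e-01,1.18580184e-01
1.55701700e-01,2.03944321e-01,1.05218154e-01
1.63670879e-01,1.90373504e-01,9.37880857e-02
1.72047939e-01,1.78462620e-01,8.40170005e-02
1.80853757e-01,1.67978906e-01,7.56697441e-02
1.90110278e-01,1.58722187e-01,6.85437976e-02
1.99840569e-01,1.50520375e-01,6.24647927e-02
2.10068880e-01,1.43225589e-01,5.72826381e-02
2.20820699e-01,1.36710798e-01,5.28681742e-02
2.32122822e-01,1.30866926e-01,4.91102849e-02
2.44003413e-01,1.25600351e-01,4.59134042e-02
2.56492082e-01,1.20830743e-01,4.31953643e-02
2.69619950e-01,1.16489212e-01,4.08855389e-02
2.83419733e-01,1.12516694e-01,3.89232407e-02
2.97925822e-01,1.08862570e-01,3.72563401e-02
3.13174366e-01,1.05483475e-01,3.58400736e-02
3.29203366e-01,1.02342272e-01,3.46360160e-02
3.46052769e-01,9.94071642e-02,3.36111956e-02
3.63764564e-01,9.66509371e-02,3.27373309e-02
3.82382889e-01,9.40503046e-02,3.19901737e-02
4.01954145e-01,9.15853461e-02,3.13489432e-02
4.22527103e-01,8.92390245e-02,3.07958390e-02
4.44153034e-01,8.69967714e-02,3.03156224e-02
4.66885831e-01,8.48461326e-02,2.98952556e-02
4.90782146e-01,8.27764627e-02,2.95235929e-02
5.15901531e-01,8.07786653e-02,2.91911141e-02
5.42306584e-01,7.88449688e-02,2.88896965e-02
5.70063111e-01,7.69687364e-02,2.86124190e-02
5.99240281e-01,7.51443019e-02,2.83533939e-02
6.29910808e-01,7.33668311e-02,2.81076232e-02
6.62151125e-01,7.16322016e-02,2.78708753e-02
6.96041577e-01,6.99369019e-02,2.76395787e-02
7.31666622e-01,6.82779437e-02,2.74107323e-02
7.69115040e-01,6.66527879e-02,2.71818275e-02
8.08480157e-01,6.50592810e-02,2.69507817e-02
8.49860072e-01,6.34956006e-02,2.67158817e-02
8.93357910e-01,6.19602087e-02,2.64757347e-02
9.39082069e-01,6.04518120e-02,2.62292262e-02
9.87146497e-01,5.89693274e-02,2.59754839e-02
1.03767098e+00,5.75118523e-02,2.57138470e-02
1.09078142e+00,5.60786392e-02,2.54438384e-02
1.14661018e+00,5.46690735e-02,2.51651420e-02
1.20529638e+00,5.32826542e-02,2.48775818e-02
1.26698629e+00,5.19189775e-02,2.45811042e-02
1.33183362e+00,5.05777218e-02,2.42757624e-02
1.40000000e+00,4.92586352e-02,2.39617022e-02
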