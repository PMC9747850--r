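# element Al (Z=13, A=26.982)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,2.51341938e+01,2.49518492e+01
1.05118235e-02,2.16614111e+01,2.14795797e+01
1.10498434e-02,1.86662205e+01,1.84849252e+01
1.16154003e-02,1.60837246e+01,1.59029893e+01
1.22099038e-02,1.38577351e+01,1.36775845e+01
1.28348354e-02,1.19396190e+01,1.17600787e+01
1.34917525e-02,1.02872949e+01,1.01083914e+01
1.41822921e-02,8.86436194e+00,8.68612274e+00
1.49081752e-02,7.63934223e+00,7.46179572e+00
1.56712107e-02,6.58502361e+00,6.40819910e+00
1.64733001e-02,5.67788878e+00,5.50181653e+00
1.73164423e-02,4.89761991e+00,4.72233113e+00
1.82027386e-02,4.22666885e+00,4.05219568e+00
1.91343975e-02,3.64988429e+00,3.47625980e+00
2.01137410e-02,3.15418850e+00,2.98144671e+00
2.11432096e-02,2.72829713e+00,2.55647294e+00
2.22253688e-02,2.36247630e+00,2.19160552e+00
2.33629154e-02,2.04833228e+00,1.87845160e+00
2.45586844e-02,1.77862925e+00,1.60977620e+00
2.58156556e-02,1.54713159e+00,1.37934450e+00
2.71369616e-02,1.34841499e+00,1.18173298e+00
2.85258951e-02,1.17785504e+00,1.01231794e+00
2.99859175e-02,1.03158522e+00,8.67233553e-01
3.15206672e-02,9.06155294e-01,7.43030197e-01
3.31339691e-02,7.98599287e-01,6.36742446e-01
3.48298436e-02,7.06368219e-01,5.45821810e-01
3.66125169e-02,6.27272123e-01,4.68078729e-01
3.84864316e-02,5.59430012e-01,4.01632536e-01
4.04562577e-02,5.01226754e-01,3.44868331e-01
4.25269041e-02,4.51275900e-01,2.96399796e-01
4.47035311e-02,4.08387657e-01,2.55037167e-01
4.69915629e-02,3.71541299e-01,2.19759631e-01
4.93967017e-02,3.39861408e-01,1.89691570e-01
5.19249410e-02,3.12597420e-01,1.64082095e-01
5.45825816e-02,2.89106029e-01,1.42287446e-01
5.73762465e-02,2.68836035e-01,1.23755838e-01
6.03128978e-02,2.51315321e-01,1.08014431e-01
6.33998537e-02,2.36139652e-01,9.46581304e-02
6.66448073e-02,2.22963044e-01,8.33399498e-02
7.00558453e-02,2.11489493e-01,7.37627394e-02
7.36414682e-02,2.01465859e-01,6.56720745e-02
7.74106118e-02,1.92675764e-01,5.88501500e-02
8.13726689e-02,1.84934346e-01,5.31105391e-02
8.55375135e-02,1.78083756e-01,4.82936943e-02
8.99155246e-02,1.71989295e-01,4.42630889e-02
9.45176126e-02,1.66536097e-01,4.09019065e-02
9.93552463e-02,1.61626285e-01,3.81102040e-02
1.04440482e-01,1.57176528e-01,3.58024793e-02
1.09785991e-01,1.53115949e-01,3.39055884e-02
1.15405096e-01,1.49384330e-01,3.23569605e-02
1.21311800e-01,1.45930573e-01,3.11030710e-02
1.27520824e-01,1.42711377e-01,3.00981338e-02
1.34047639e-01,1.39690107e-01,2.93029828e-02
1.40908513e-01,1.36835825e-01,2.86841149e-02
1.48120542e-01,1.34122456e-01,2.82128724e-02
1.55701700e-01,1.31528073e-01,2.78647428e-02
1.63670879e-01,1.29034286e-01,2.76187612e-02
1.72047939e-01,1.26625716e-01,2.74569991e-02
1.80853757e-01,1.24289546e-01,2.73641273e-02
1.90110278e-01,1.22015131e-01,2.73270426e-02
1.99840569e-01,1.19793671e-01,2.73345482e-02
2.10068880e-01,1.17617922e-01,2.73770807e-02
2.20820699e-01,1.15481957e-01,2.74464764e-02
2.32122822e-01,1.13380951e-01,2.75357708e-02
2.44003413e-01,1.11311011e-01,2.76390280e-02
2.56492082e-01,1.09269013e-01,2.77511935e-02
2.69619950e-01,1.07252479e-01,2.78679680e-02
2.83419733e-01,1.05259462e-01,2.79857001e-02
2.97925822e-01,1.03288454e-01,2.81012934e-02
3.13174366e-01,1.01338301e-01,2.82121267e-02
3.29203366e-01,9.94081407e-02,2.83159863e-02
3.46052769e-01,9.74973433e-02,2.84110073e-02
3.63764564e-01,9.56054628e-02,2.84956236e-02
3.82382889e-01,9.37321988e-02,2.85685246e-02
4.01954145e-01,9.18773633e-02,2.86286194e-02
4.22527103e-01,9.00408548e-02,2.86750047e-02
4.44153034e-01,8.82226360e-02,2.87069393e-02
4.66885831e-01,8.64227169e-02,2.87238209e-02
4.90782146e-01,8.46411417e-02,2.87251679e-02
5.15901531e-01,8.28779782e-02,2.87106034e-02
5.42306584e-01,8.11333102e-02,2.86798423e-02
5.70063111e-01,7.94072316e-02,2.86326801e-02
5.99240281e-01,7.76998430e-02,2.85689849e-02
6.29910808e-01,7.60112489e-02,2.84886893e-02
6.62151125e-01,7.43415563e-02,2.83917852e-02
6.96041577e-01,7.26908741e-02,2.82783190e-02
7.31666622e-01,7.10593130e-02,2.81483877e-02
7.69115040e-01,6.94469858e-02,2.80021360e-02
8.08480157e-01,6.78540077e-02,2.78397538e-02
8.49860072e-01,6.62804973e-02,2.76614744e-02
8.93357910e-01,6.47265769e-02,2.74675723e-02
9.39082069e-01,6.31923729e-02,2.72583618e-02
9.87146497e-01,6.16780165e-02,2.70341955e-02
1.03767098e+00,6.01836433e-02,2.67954628e-02
1.09078142e+00,5.87093936e-02,2.65425879e-02
1.14661018e+00,5.72554121e-02,2.62760290e-02
1.20529638e+00,5.58218470e-02,2.59962754e-02
1.26698629e+00,5.44088496e-02,2.57038463e-02
1.33183362e+00,5.30165731e-02,2.53992882e-02
1.40000000e+00,5.16451716e-02,2.50831732e-02
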