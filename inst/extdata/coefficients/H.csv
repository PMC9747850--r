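# element H (Z=1, A=1.008)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,3.82639130e-01,7.17969757e-03
1.05118235e-02,3.81920056e-01,7.51718591e-03
1.10498434e-02,3.81168008e-01,7.86902575e-03
1.16154003e-02,3.80381668e-01,8.23567893e-03
1.22099038e-02,3.79559685e-01,8.61760724e-03
1.28348354e-02,3.78700674e-01,9.01527075e-03
1.34917525e-02,3.77803221e-01,9.42912571e-03
1.41822921e-02,3.76865881e-01,9.85962250e-03
1.49081752e-02,3.75887181e-01,1.03072032e-02
1.56712107e-02,3.74865626e-01,1.07722991e-02
1.64733001e-02,3.73799695e-01,1.12553279e-02
1.73164423e-02,3.72687850e-01,1.17566906e-02
1.82027386e-02,3.71528536e-01,1.22767683e-02
1.91343975e-02,3.70320186e-01,1.28159193e-02
2.01137410e-02,3.69061225e-01,1.33744744e-02
2.11432096e-02,3.67750074e-01,1.39527343e-02
2.22253688e-02,3.66385157e-01,1.45509645e-02
2.33629154e-02,3.64964905e-01,1.51693918e-02
2.45586844e-02,3.63487763e-01,1.58081996e-02
2.58156556e-02,3.61952195e-01,1.64675232e-02
2.71369616e-02,3.60356693e-01,1.71474458e-02
2.85258951e-02,3.58699785e-01,1.78479932e-02
2.99859175e-02,3.56980041e-01,1.85691290e-02
3.15206672e-02,3.55196082e-01,1.93107503e-02
3.31339691e-02,3.53346590e-01,2.00726828e-02
3.48298436e-02,3.51430317e-01,2.08546759e-02
3.66125169e-02,3.49446095e-01,2.16563988e-02
3.84864316e-02,3.47392844e-01,2.24774355e-02
4.04562577e-02,3.45269585e-01,2.33172820e-02
4.25269041e-02,3.43075451e-01,2.41753416e-02
4.47035311e-02,3.40809694e-01,2.50509225e-02
4.69915629e-02,3.38471697e-01,2.59432353e-02
4.93967017e-02,3.36060988e-01,2.68513906e-02
5.19249410e-02,3.33577245e-01,2.77743981e-02
5.45825816e-02,3.31020309e-01,2.87111662e-02
5.73762465e-02,3.28390193e-01,2.96605020e-02
6.03128978e-02,3.25687093e-01,3.06211130e-02
6.33998537e-02,3.22911389e-01,3.15916090e-02
6.66448073e-02,3.20063663e-01,3.25705057e-02
7.00558453e-02,3.17144695e-01,3.35562287e-02
7.36414682e-02,3.14155475e-01,3.45471190e-02
7.74106118e-02,3.11097203e-01,3.55414396e-02
8.13726689e-02,3.07971293e-01,3.65373827e-02
8.55375135e-02,3.04779374e-01,3.75330784e-02
8.99155246e-02,3.01523284e-01,3.85266039e-02
9.45176126e-02,2.98205077e-01,3.95159940e-02
9.93552463e-02,2.94827006e-01,4.04992517e-02
1.04440482e-01,2.91391528e-01,4.14743603e-02
1.09785991e-01,2.87901287e-01,4.24392952e-02
1.15405096e-01,2.84359106e-01,4.33920359e-02
1.21311800e-01,2.80767977e-01,4.43305790e-02
1.27520824e-01,2.77131042e-01,4.52529501e-02
1.34047639e-01,2.73451583e-01,4.61572161e-02
1.40908513e-01,2.69732999e-01,4.70414966e-02
1.48120542e-01,2.65978790e-01,4.79039745e-02
1.55701700e-01,2.62192538e-01,4.87429065e-02
1.63670879e-01,2.58377883e-01,4.95566316e-02
1.72047939e-01,2.54538506e-01,5.03435789e-02
1.80853757e-01,2.50678102e-01,5.11022743e-02
1.90110278e-01,2.46800363e-01,5.18313453e-02
1.99840569e-01,2.42908954e-01,5.25295244e-02
2.10068880e-01,2.39007494e-01,5.31956519e-02
2.20820699e-01,2.35099534e-01,5.38286760e-02
2.32122822e-01,2.31188540e-01,5.44276527e-02
2.44003413e-01,2.27277873e-01,5.49917434e-02
2.56492082e-01,2.23370777e-01,5.55202123e-02
2.69619950e-01,2.19470364e-01,5.60124222e-02
2.83419733e-01,2.15579601e-01,5.64678298e-02
2.97925822e-01,2.11701301e-01,5.68859804e-02
3.13174366e-01,2.07838116e-01,5.72665019e-02
3.29203366e-01,2.03992532e-01,5.76090989e-02
3.46052769e-01,2.00166868e-01,5.79135470e-02
3.63764564e-01,1.96363271e-01,5.81796870e-02
3.82382889e-01,1.92583721e-01,5.84074192e-02
4.01954145e-01,1.88830033e-01,5.85966989e-02
4.22527103e-01,1.85103864e-01,5.87475323e-02
4.44153034e-01,1.81406716e-01,5.88599725e-02
4.66885831e-01,1.77739949e-01,5.89341175e-02
4.90782146e-01,1.74104784e-01,5.89701077e-02
5.15901531e-01,1.70502321e-01,5.89681252e-02
5.42306584e-01,1.66933542e-01,5.89283934e-02
5.70063111e-01,1.63399326e-01,5.88511772e-02
5.99240281e-01,1.59900460e-01,5.87367840e-02
6.29910808e-01,1.56437649e-01,5.85855651e-02
6.62151125e-01,1.53011526e-01,5.83979179e-02
6.96041577e-01,1.49622667e-01,5.81742873e-02
7.31666622e-01,1.46271593e-01,5.79151685e-02
7.69115040e-01,1.42958787e-01,5.76211088e-02
8.08480157e-01,1.39684697e-01,5.72927097e-02
8.49860072e-01,1.36449743e-01,5.69306289e-02
8.93357910e-01,1.33254328e-01,5.65355815e-02
9.39082069e-01,1.30098839e-01,5.61083409e-02
9.87146497e-01,1.26983651e-01,5.56497398e-02
1.03767098e+00,1.23909135e-01,5.51606694e-02
1.09078142e+00,1.20875653e-01,5.46420793e-02
1.14661018e+00,1.17883569e-01,5.40949762e-02
1.20529638e+00,1.14933240e-01,5.35204214e-02
1.26698629e+00,1.12025024e-01,5.29195291e-02
1.33183362e+00,1.09159273e-01,5.22934629e-02
1.40000000e+00,1.06336338e-01,5.16434322e-02
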