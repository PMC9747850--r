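# element Si (Z=14, A=28.085)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,3.26005260e+01,3.24118671e+01
1.05118235e-02,2.81227339e+01,2.79346060e+01
1.10498434e-02,2.42560470e+01,2.40684738e+01
1.16154003e-02,2.09180863e+01,2.07310924e+01
1.22099038e-02,1.80374366e+01,1.78510476e+01
1.28348354e-02,1.55522063e+01,1.53664488e+01
1.34917525e-02,1.34087736e+01,1.32236749e+01
1.41822921e-02,1.15606955e+01,1.13762841e+01
1.49081752e-02,9.96775948e+00,9.78406481e+00
1.56712107e-02,8.59515821e+00,8.41221055e+00
1.64733001e-02,7.41277235e+00,7.23060301e+00
1.73164423e-02,6.39454737e+00,6.21318862e+00
1.82027386e-02,5.51795200e+00,5.33743710e+00
1.91343975e-02,4.76350792e+00,4.58387109e+00
2.01137410e-02,4.11438143e+00,3.93565787e+00
2.11432096e-02,3.55602901e+00,3.37825482e+00
2.22253688e-02,3.07588968e+00,2.89910193e+00
2.33629154e-02,2.66311827e+00,2.48735490e+00
2.45586844e-02,2.30835402e+00,2.13365386e+00
2.58156556e-02,2.00351996e+00,1.82992267e+00
2.71369616e-02,1.74148903e+00,1.56903509e+00
2.85258951e-02,1.51620329e+00,1.34493392e+00
2.99859175e-02,1.32284072e+00,1.15279782e+00
3.15206672e-02,1.15689929e+00,9.88125430e-01
3.31339691e-02,1.01450425e+00,8.47042568e-01
3.48298436e-02,8.92321692e-01,7.26215818e-01
3.66125169e-02,7.87483861e-01,6.22777855e-01
3.84864316e-02,6.97524724e-01,5.34262974e-01
4.04562577e-02,6.20324306e-01,4.58551441e-01
4.25269041e-02,5.54060676e-01,3.93821462e-01
4.47035311e-02,4.97168516e-01,3.38507744e-01
4.69915629e-02,4.48303385e-01,2.91265762e-01
4.93967017e-02,4.06310917e-01,2.50940939e-01
5.19249410e-02,3.70200254e-01,2.16542082e-01
5.45825816e-02,3.39121168e-01,1.87218494e-01
5.73762465e-02,3.12344341e-01,1.62240249e-01
6.03128978e-02,2.89244384e-01,1.40981215e-01
6.33998537e-02,2.69285223e-01,1.22904424e-01
6.66448073e-02,2.52007509e-01,1.07549491e-01
7.00558453e-02,2.37017794e-01,9.45217838e-02
7.36414682e-02,2.23979214e-01,8.34831089e-02
7.74106118e-02,2.12603482e-01,7.41437014e-02
8.13726689e-02,2.02643995e-01,6.62553405e-02
8.55375135e-02,1.93889917e-01,5.96054338e-02
8.99155246e-02,1.86161095e-01,5.40119348e-02
9.45176126e-02,1.79303680e-01,4.93189792e-02
9.93552463e-02,1.73186383e-01,4.53931389e-02
1.04440482e-01,1.67697244e-01,4.21202070e-02
1.09785991e-01,1.62740865e-01,3.94024412e-02
1.15405096e-01,1.58236038e-01,3.71561981e-02
1.21311800e-01,1.54113702e-01,3.53099075e-02
1.27520824e-01,1.50315193e-01,3.38023344e-02
1.34047639e-01,1.46790745e-01,3.25810918e-02
1.40908513e-01,1.43498196e-01,3.16013660e-02
1.48120542e-01,1.40401889e-01,3.08248261e-02
1.55701700e-01,1.37471714e-01,3.02186895e-02
1.63670879e-01,1.34682305e-01,2.97549235e-02
1.72047939e-01,1.32012331e-01,2.94095608e-02
1.80853757e-01,1.29443905e-01,2.91621150e-02
1.90110278e-01,1.26962064e-01,2.89950795e-02
1.99840569e-01,1.24554333e-01,2.88934995e-02
2.10068880e-01,1.22210342e-01,2.88446055e-02
2.20820699e-01,1.19921507e-01,2.88374991e-02
2.32122822e-01,1.17680747e-01,2.88628851e-02
2.44003413e-01,1.15482250e-01,2.89128409e-02
2.56492082e-01,1.13321270e-01,2.89806196e-02
2.69619950e-01,1.11193950e-01,2.90604813e-02
2.83419733e-01,1.09097177e-01,2.91475483e-02
2.97925822e-01,1.07028452e-01,2.92376807e-02
3.13174366e-01,1.04985787e-01,2.93273706e-02
3.29203366e-01,1.02967612e-01,2.94136503e-02
3.46052769e-01,1.00972699e-01,2.94940145e-02
3.63764564e-01,9.90000986e-02,2.95663534e-02
3.82382889e-01,9.70490830e-02,2.96288955e-02
4.01954145e-01,9.51191051e-02,2.96801587e-02
4.22527103e-01,9.32097596e-02,2.97189086e-02
4.44153034e-01,9.13207534e-02,2.97441237e-02
4.66885831e-01,8.94518810e-02,2.97549649e-02
4.90782146e-01,8.76030046e-02,2.97507504e-02
5.15901531e-01,8.57740389e-02,2.97309349e-02
5.42306584e-01,8.39649386e-02,2.96950913e-02
5.70063111e-01,8.21756893e-02,2.96428966e-02
5.99240281e-01,8.04063001e-02,2.95741193e-02
6.29910808e-01,7.86567990e-02,2.94886095e-02
6.62151125e-01,7.69272287e-02,2.93862908e-02
6.96041577e-01,7.52176441e-02,2.92671534e-02
7.31666622e-01,7.35281110e-02,2.91312491e-02
7.69115040e-01,7.18587047e-02,2.89786863e-02
8.08480157e-01,7.02095097e-02,2.88096264e-02
8.49860072e-01,6.85806188e-02,2.86242812e-02
8.93357910e-01,6.69721337e-02,2.84229097e-02
9.39082069e-01,6.53841640e-02,2.82058158e-02
9.87146497e-01,6.38168274e-02,2.79733465e-02
1.03767098e+00,6.22702491e-02,2.77258894e-02
1.09078142e+00,6.07445614e-02,2.74638709e-02
1.14661018e+00,5.92399032e-02,2.71877537e-02
1.20529638e+00,5.77564186e-02,2.68980353e-02
1.26698629e+00,5.62942565e-02,2.65952449e-02
1.33183362e+00,5.48535687e-02,2.62799416e-02
1.40000000e+00,5.34345093e-02,2.59527115e-02
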