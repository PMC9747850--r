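# element P (Z=15, A=30.974)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,3.90320390e+01,3.88487580e+01
1.05118235e-02,3.37086711e+01,3.35259058e+01
1.10498434e-02,2.91049157e+01,2.89226893e+01
1.16154003e-02,2.51248309e+01,2.49431673e+01
1.22099038e-02,2.16850836e+01,2.15040077e+01
1.28348354e-02,1.87133168e+01,1.85328544e+01
1.34917525e-02,1.61467251e+01,1.59669028e+01
1.41822921e-02,1.39308116e+01,1.37516570e+01
1.49081752e-02,1.20183052e+01,1.18398469e+01
1.56712107e-02,1.03682162e+01,1.01904835e+01
1.64733001e-02,8.94501360e+00,8.76803708e+00
1.73164423e-02,7.71790911e+00,7.54172008e+00
1.82027386e-02,6.66023290e+00,6.48486367e+00
1.91343975e-02,5.74889082e+00,5.57437463e+00
2.01137410e-02,4.96389187e+00,4.79026290e+00
2.11432096e-02,4.28793728e+00,4.11523063e+00
2.22253688e-02,3.70606315e+00,3.53431482e+00
2.33629154e-02,3.20532986e+00,3.03457670e+00
2.45586844e-02,2.77455210e+00,2.60483185e+00
2.58156556e-02,2.40406448e+00,2.23541567e+00
2.71369616e-02,2.08501830e+00,1.91748024e+00
2.85258951e-02,1.81007808e+00,1.64369081e+00
2.99859175e-02,1.57413384e+00,1.40893809e+00
3.15206672e-02,1.37167724e+00,1.20771436e+00
3.31339691e-02,1.19797042e+00,1.03528231e+00
3.48298436e-02,1.04893913e+00,8.87568187e-01
3.66125169e-02,9.21080675e-01,7.61069691e-01
3.84864316e-02,8.11384384e-01,6.52776488e-01
4.04562577e-02,7.17263155e-01,5.60101703e-01
4.25269041e-02,6.36494389e-01,4.80822869e-01
4.47035311e-02,5.67169103e-01,4.13031032e-01
4.69915629e-02,5.07648093e-01,3.55086902e-01
4.93967017e-02,4.56524159e-01,3.05583076e-01
5.19249410e-02,4.12589586e-01,2.63311513e-01
5.45825816e-02,3.74808138e-01,2.27235521e-01
5.73762465e-02,3.42290953e-01,1.96465650e-01
6.03128978e-02,3.14275799e-01,1.70238942e-01
6.33998537e-02,2.90109223e-01,1.47901078e-01
6.66448073e-02,2.69231198e-01,1.28891024e-01
7.00558453e-02,2.51161921e-01,1.12727828e-01
7.36414682e-02,2.35490460e-01,9.89992629e-02
7.74106118e-02,2.21864992e-01,8.73520734e-02
8.13726689e-02,2.09984420e-01,7.74835898e-02
8.55375135e-02,1.99591167e-01,6.91345263e-02
8.99155246e-02,1.90464981e-01,6.20827953e-02
9.45176126e-02,1.82417624e-01,5.61381979e-02
9.93552463e-02,1.75288302e-01,5.11378650e-02
1.04440482e-01,1.68939751e-01,4.69423470e-02
1.09785991e-01,1.63254862e-01,4.34322590e-02
1.15405096e-01,1.58133805e-01,4.05054033e-02
1.21311800e-01,1.53491539e-01,3.80743031e-02
1.27520824e-01,1.49255693e-01,3.60640887e-02
1.34047639e-01,1.45364738e-01,3.44106856e-02
1.40908513e-01,1.41766421e-01,3.30592631e-02
1.48120542e-01,1.38416421e-01,3.19629051e-02
1.55701700e-01,1.35277198e-01,3.10814720e-02
1.63670879e-01,1.32317003e-01,3.03806266e-02
1.72047939e-01,1.29509029e-01,2.98309998e-02
1.80853757e-01,1.26830687e-01,2.94074766e-02
1.90110278e-01,1.24262975e-01,2.90885852e-02
1.99840569e-01,1.21789950e-01,2.88559738e-02
2.10068880e-01,1.19398265e-01,2.86939628e-02
2.20820699e-01,1.17076776e-01,2.85891611e-02
2.32122822e-01,1.14816204e-01,2.85301382e-02
2.44003413e-01,1.12608850e-01,2.85071424e-02
2.56492082e-01,1.10448341e-01,2.85118604e-02
2.69619950e-01,1.08329426e-01,2.85372104e-02
2.83419733e-01,1.06247792e-01,2.85771652e-02
2.97925822e-01,1.04199909e-01,2.86266006e-02
3.13174366e-01,1.02182902e-01,2.86811650e-02
3.29203366e-01,1.00194439e-01,2.87371684e-02
3.46052769e-01,9.82326376e-02,2.87914866e-02
3.63764564e-01,9.62959826e-02,2.88414792e-02
3.82382889e-01,9.43832634e-02,2.88849203e-02
4.01954145e-01,9.24935162e-02,2.89199380e-02
4.22527103e-01,9.06259783e-02,2.89449641e-02
4.44153034e-01,8.87800490e-02,2.89586903e-02
4.66885831e-01,8.69552587e-02,2.89600316e-02
4.90782146e-01,8.51512432e-02,2.89480950e-02
5.15901531e-01,8.33677223e-02,2.89221535e-02
5.42306584e-01,8.16044836e-02,2.88816241e-02
5.70063111e-01,7.98613692e-02,2.88260488e-02
5.99240281e-01,7.81382652e-02,2.87550798e-02
6.29910808e-01,7.64350935e-02,2.86684665e-02
6.62151125e-01,7.47518060e-02,2.85660451e-02
6.96041577e-01,7.30883796e-02,2.84477295e-02
7.31666622e-01,7.14448128e-02,2.83135045e-02
7.69115040e-01,6.98211229e-02,2.81634197e-02
8.08480157e-01,6.82173442e-02,2.79975843e-02
8.49860072e-01,6.66335266e-02,2.78161633e-02
8.93357910e-01,6.50697338e-02,2.76193737e-02
9.39082069e-01,6.35260429e-02,2.74074811e-02
9.87146497e-01,6.20025428e-02,2.71807974e-02
1.03767098e+00,6.04993338e-02,2.69396776e-02
1.09078142e+00,5.90165260e-02,2.66845174e-02
1.14661018e+00,5.75542386e-02,2.64157509e-02
1.20529638e+00,5.61125983e-02,2.61338478e-02
1.26698629e+00,5.46917382e-02,2.58393111e-02
1.33183362e+00,5.32917963e-02,2.55326740e-02
1.40000000e+00,5.19129138e-02,2.52144977e-02
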