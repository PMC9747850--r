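# element Ca (Z=20, A=40.078)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,9.17175301e+01,9.15286668e+01
1.05118235e-02,7.96860959e+01,7.94977641e+01
1.10498434e-02,6.92034293e+01,6.90156527e+01
1.16154003e-02,6.00744601e+01,5.98872635e+01
1.22099038e-02,5.21280773e+01,5.19414863e+01
1.28348354e-02,4.52144874e+01,4.50285286e+01
1.34917525e-02,3.92023302e+01,3.90170310e+01
1.41822921e-02,3.39765767e+01,3.37919656e+01
1.49081752e-02,2.94365463e+01,2.92526525e+01
1.56712107e-02,2.54941585e+01,2.53110126e+01
1.64733001e-02,2.20723933e+01,2.18900265e+01
1.73164423e-02,1.91039345e+01,1.89223792e+01
1.82027386e-02,1.65234676e+01,1.63427571e+01
1.91343975e-02,1.42880977e+01,1.41082662e+01
2.01137410e-02,1.23540459e+01,1.21751287e+01
2.11432096e-02,1.06812801e+01,1.05033133e+01
2.22253688e-02,9.23499042e+00,9.05801110e+00
2.33629154e-02,7.98494539e+00,7.80899157e+00
2.45586844e-02,6.90488719e+00,6.72999773e+00
2.58156556e-02,5.97201731e+00,5.79823192e+00
2.71369616e-02,5.16340119e+00,4.99076038e+00
2.85258951e-02,4.46079277e+00,4.28933780e+00
2.99859175e-02,3.85631725e+00,3.68609009e+00
3.15206672e-02,3.33633811e+00,3.16738137e+00
3.31339691e-02,2.88909991e+00,2.72145676e+00
3.48298436e-02,2.50447051e+00,2.33818464e+00
3.66125169e-02,2.17371852e+00,2.00883403e+00
3.84864316e-02,1.88932094e+00,1.72588227e+00
4.04562577e-02,1.64479710e+00,1.48284894e+00
4.25269041e-02,1.43456529e+00,1.27415244e+00
4.47035311e-02,1.25381886e+00,1.09498617e+00
4.69915629e-02,1.09841947e+00,9.41211679e-01
4.93967017e-02,9.64804740e-01,8.09266403e-01
5.19249410e-02,8.49908746e-01,6.96084070e-01
5.45825816e-02,7.51093308e-01,5.99026032e-01
5.73762465e-02,6.66088772e-01,5.15822028e-01
6.03128978e-02,5.92942919e-01,4.44519092e-01
6.33998537e-02,5.29976918e-01,3.83437500e-01
6.66448073e-02,4.75747343e-01,3.31132790e-01
7.00558453e-02,4.29013436e-01,2.86363017e-01
7.36414682e-02,3.88708892e-01,2.48060545e-01
7.74106118e-02,3.53917543e-01,2.15307727e-01
8.13726689e-02,3.23852411e-01,1.87315966e-01
8.55375135e-02,2.97837667e-01,1.63407673e-01
8.99155246e-02,2.75293084e-01,1.43000727e-01
9.45176126e-02,2.55720661e-01,1.25595108e-01
9.93552463e-02,2.38693095e-01,1.10761373e-01
1.04440482e-01,2.23843866e-01,9.81307535e-02
1.09785991e-01,2.10858698e-01,8.73866245e-02
1.15405096e-01,1.99468213e-01,7.82571715e-02
1.21311800e-01,1.89441610e-01,7.05090800e-02
1.27520824e-01,1.80581222e-01,6.39421099e-02
1.34047639e-01,1.72717841e-01,5.83844307e-02
1.40908513e-01,1.65706693e-01,5.36886115e-02
1.48120542e-01,1.59423975e-01,4.97281747e-02
1.55701700e-01,1.53763878e-01,4.63946340e-02
1.63670879e-01,1.48636031e-01,4.35949507e-02
1.72047939e-01,1.43963298e-01,4.12493472e-02
1.80853757e-01,1.39679885e-01,3.92894298e-02
1.90110278e-01,1.35729718e-01,3.76565760e-02
1.99840569e-01,1.32065042e-01,3.63005501e-02
2.10068880e-01,1.28645222e-01,3.51783136e-02
2.20820699e-01,1.25435711e-01,3.42530043e-02
2.32122822e-01,1.22407164e-01,3.34930594e-02
2.44003413e-01,1.19534679e-01,3.28714630e-02
2.56492082e-01,1.16797142e-01,3.23650994e-02
2.69619950e-01,1.14176667e-01,3.19541978e-02
2.83419733e-01,1.11658119e-01,3.16218566e-02
2.97925822e-01,1.09228699e-01,3.13536335e-02
3.13174366e-01,1.06877594e-01,3.11371947e-02
3.29203366e-01,1.04595678e-01,3.09620133e-02
3.46052769e-01,1.02375250e-01,3.08191109e-02
3.63764564e-01,1.00209819e-01,3.07008356e-02
3.82382889e-01,9.80939160e-02,3.06006718e-02
4.01954145e-01,9.60229336e-02,3.05130774e-02
4.22527103e-01,9.39929939e-02,3.04333442e-02
4.44153034e-01,9.20008326e-02,3.03574784e-02
4.66885831e-01,9.00437029e-02,3.02820991e-02
4.90782146e-01,8.81192939e-02,3.02043510e-02
5.15901531e-01,8.62256625e-02,3.01218301e-02
5.42306584e-01,8.43611752e-02,3.00325211e-02
5.70063111e-01,8.25244604e-02,2.99347432e-02
5.99240281e-01,8.07143677e-02,2.98271050e-02
6.29910808e-01,7.89299342e-02,2.97084659e-02
6.62151125e-01,7.71703566e-02,2.95779033e-02
6.96041577e-01,7.54349675e-02,2.94346849e-02
7.31666622e-01,7.37232159e-02,2.92782456e-02
7.69115040e-01,7.20346507e-02,2.91081674e-02
8.08480157e-01,7.03689071e-02,2.89241629e-02
8.49860072e-01,6.87256948e-02,2.87260605e-02
8.93357910e-01,6.71047886e-02,2.85137925e-02
9.39082069e-01,6.55060192e-02,2.82873845e-02
9.87146497e-01,6.39292669e-02,2.80469460e-02
1.03767098e+00,6.23744543e-02,2.77926623e-02
1.09078142e+00,6.08415411e-02,2.75247875e-02
1.14661018e+00,5.93305191e-02,2.72436379e-02
1.20529638e+00,5.78414074e-02,2.69495859e-02
1.26698629e+00,5.63742480e-02,2.66430545e-02
1.33183362e+00,5.49291022e-02,2.63245126e-02
1.40000000e+00,5.35060466e-02,2.59944695e-02
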