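# element Mn (Z=25, A=54.938)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,1.49979720e+02,1.49807497e+02
1.05118235e-02,1.31099330e+02,1.30927592e+02
1.10498434e-02,1.14527504e+02,1.14356272e+02
1.16154003e-02,9.99910300e+01,9.98203271e+01
1.22099038e-02,8.72472371e+01,8.70770863e+01
1.28348354e-02,7.60804542e+01,7.59108799e+01
1.34917525e-02,6.62690783e+01,6.61001055e+01
1.41822921e-02,5.76771027e+01,5.75087573e+01
1.49081752e-02,5.01749392e+01,5.00072481e+01
1.56712107e-02,4.36289029e+01,4.34618937e+01
1.64733001e-02,3.79209419e+01,3.77546432e+01
1.73164423e-02,3.29462157e+01,3.27806570e+01
1.82027386e-02,2.86126827e+01,2.84478943e+01
1.91343975e-02,2.48395764e+01,2.46755896e+01
2.01137410e-02,2.15560591e+01,2.13929060e+01
2.11432096e-02,1.87000314e+01,1.85377449e+01
2.22253688e-02,1.62170813e+01,1.60556953e+01
2.33629154e-02,1.40595561e+01,1.38991053e+01
2.45586844e-02,1.21857470e+01,1.20262667e+01
2.58156556e-02,1.05591612e+01,1.04006877e+01
2.71369616e-02,9.14684528e+00,8.98941558e+00
2.85258951e-02,7.91961496e+00,7.76326662e+00
2.99859175e-02,6.84936945e+00,6.69414074e+00
3.15206672e-02,5.92529813e+00,5.77122790e+00
3.31339691e-02,5.12758586e+00,4.97471348e+00
3.48298436e-02,4.43908006e+00,4.28744538e+00
3.66125169e-02,3.84493596e+00,3.69457919e+00
3.84864316e-02,3.33230860e+00,3.18327026e+00
4.04562577e-02,2.89008575e+00,2.74240658e+00
4.25269041e-02,2.50865612e+00,2.36237699e+00
4.47035311e-02,2.17970841e+00,2.03487021e+00
4.69915629e-02,1.89605695e+00,1.75270049e+00
4.93967017e-02,1.65149064e+00,1.50965654e+00
5.19249410e-02,1.44064189e+00,1.30037047e+00
5.45825816e-02,1.25887315e+00,1.12020428e+00
5.73762465e-02,1.10217844e+00,9.65151459e-01
6.03128978e-02,9.67098197e-01,8.31751758e-01
6.33998537e-02,8.50645391e-01,7.17017329e-01
6.66448073e-02,7.50241596e-01,6.18368802e-01
7.00558453e-02,6.63661632e-01,5.33579915e-01
7.36414682e-02,5.88985635e-01,4.60729590e-01
7.74106118e-02,5.24557575e-01,3.98160450e-01
8.13726689e-02,4.68949366e-01,3.44442931e-01
8.55375135e-02,4.20929810e-01,2.98344229e-01
8.99155246e-02,3.79437736e-01,2.58801449e-01
9.45176126e-02,3.43558775e-01,2.24898378e-01
9.93552463e-02,3.12505274e-01,1.95845413e-01
1.04440482e-01,2.85598937e-01,1.70962208e-01
1.09785991e-01,2.62255821e-01,1.49662676e-01
1.15405096e-01,2.41973373e-01,1.31442043e-01
1.21311800e-01,2.24319225e-01,1.15865651e-01
1.27520824e-01,2.08921526e-01,1.02559301e-01
1.34047639e-01,1.95460587e-01,9.12009113e-02
1.40908513e-01,1.83661664e-01,8.15133170e-02
1.48120542e-01,1.73288736e-01,7.32580589e-02
1.55701700e-01,1.64139133e-01,6.62300227e-02
1.63670879e-01,1.56038894e-01,6.02528159e-02
1.72047939e-01,1.48838769e-01,5.51747815e-02
1.80853757e-01,1.42410772e-01,5.08655599e-02
1.90110278e-01,1.36645199e-01,4.72131261e-02
1.99840569e-01,1.31448070e-01,4.41212356e-02
2.10068880e-01,1.26738911e-01,4.15072239e-02
2.20820699e-01,1.22448853e-01,3.93001098e-02
2.32122822e-01,1.18518987e-01,3.74389628e-02
2.44003413e-01,1.14898953e-01,3.58714958e-02
2.56492082e-01,1.11545723e-01,3.45528535e-02
2.69619950e-01,1.08422547e-01,3.34445697e-02
2.83419733e-01,1.05498063e-01,3.25136687e-02
2.97925822e-01,1.02745509e-01,3.17318928e-02
3.13174366e-01,1.00142070e-01,3.10750372e-02
3.29203366e-01,9.76682965e-02,3.05223771e-02
3.46052769e-01,9.53076176e-02,3.00561762e-02
3.63764564e-01,9.30459208e-02,2.96612633e-02
3.82382889e-01,9.08711900e-02,2.93246685e-02
4.01954145e-01,8.87731973e-02,2.90353106e-02
4.22527103e-01,8.67432390e-02,2.87837291e-02
4.44153034e-01,8.47739098e-02,2.85618538e-02
4.66885831e-01,8.28589109e-02,2.83628073e-02
4.90782146e-01,8.09928851e-02,2.81807359e-02
5.15901531e-01,7.91712776e-02,2.80106648e-02
5.42306584e-01,7.73902166e-02,2.78483740e-02
5.70063111e-01,7.56464128e-02,2.76902921e-02
5.99240281e-01,7.39370731e-02,2.75334064e-02
6.29910808e-01,7.22598278e-02,2.73751850e-02
6.62151125e-01,7.06126689e-02,2.72135111e-02
6.96041577e-01,6.89938977e-02,2.70466269e-02
7.31666622e-01,6.74020800e-02,2.68730855e-02
7.69115040e-01,6.58360089e-02,2.66917099e-02
8.08480157e-01,6.42946719e-02,2.65015583e-02
8.49860072e-01,6.27772241e-02,2.63018941e-02
8.93357910e-01,6.12829649e-02,2.60921602e-02
9.39082069e-01,5.98113173e-02,2.58719575e-02
9.87146497e-01,5.83618117e-02,2.56410252e-02
1.03767098e+00,5.69340701e-02,2.53992250e-02
1.09078142e+00,5.55277937e-02,2.51465265e-02
1.14661018e+00,5.41427517e-02,2.48829947e-02
1.20529638e+00,5.27787712e-02,2.46087790e-02
1.26698629e+00,5.14357283e-02,2.43241031e-02
1.33183362e+00,5.01135410e-02,2.40292565e-02
1.40000000e+00,4.88121617e-02,2.37245860e-02
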