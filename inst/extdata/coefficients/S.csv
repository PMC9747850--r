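# element S (Z=16, A=32.060)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,4.87231212e+01,4.85342438e+01
1.05118235e-02,4.21561065e+01,4.19677606e+01
1.10498434e-02,3.64434530e+01,3.62556624e+01
1.16154003e-02,3.14872825e+01,3.13000720e+01
1.22099038e-02,2.71990484e+01,2.70124434e+01
1.28348354e-02,2.34900291e+01,2.33040563e+01
1.34917525e-02,2.02831110e+01,2.00977979e+01
1.41822921e-02,1.75112931e+01,1.73266682e+01
1.49081752e-02,1.51163810e+01,1.49324735e+01
1.56712107e-02,1.30478468e+01,1.28646872e+01
1.64733001e-02,1.12618354e+01,1.10794550e+01
1.73164423e-02,9.72029593e+00,9.53872707e+00
1.82027386e-02,8.39022588e+00,8.20950184e+00
1.91343975e-02,7.24301127e+00,7.06316633e+00
2.01137410e-02,6.25385212e+00,6.07492149e+00
2.11432096e-02,5.40126175e+00,5.22328160e+00
2.22253688e-02,4.66663090e+00,4.48963833e+00
2.33629154e-02,4.03384822e+00,3.85788122e+00
2.45586844e-02,3.48897008e+00,3.31406752e+00
2.58156556e-02,3.01993329e+00,2.84613489e+00
2.71369616e-02,2.61566370e+00,2.44300997e+00
2.85258951e-02,2.26699612e+00,2.09552832e+00
2.99859175e-02,1.96756601e+00,1.79732611e+00
3.15206672e-02,1.71045481e+00,1.54148542e+00
3.31339691e-02,1.48970686e+00,1.32205117e+00
3.48298436e-02,1.30019661e+00,1.13389829e+00
3.66125169e-02,1.13751381e+00,9.72616986e-01
3.84864316e-02,9.97864648e-01,8.34413753e-01
4.04562577e-02,8.77986281e-01,7.16025995e-01
4.25269041e-02,7.75073208e-01,6.14648350e-01
4.47035311e-02,6.86713740e-01,5.27869153e-01
4.69915629e-02,6.10835219e-01,4.53615661e-01
4.93967017e-02,5.45656801e-01,3.90106820e-01
5.19249410e-02,4.89648755e-01,3.35812564e-01
5.45825816e-02,4.41497396e-01,2.89418735e-01
5.73762465e-02,4.00074865e-01,2.49796872e-01
6.03128978e-02,3.64413115e-01,2.15978177e-01
6.33998537e-02,3.33681493e-01,1.87131106e-01
6.66448073e-02,3.07167454e-01,1.62542076e-01
7.00558453e-02,2.84259951e-01,1.41598853e-01
7.36414682e-02,2.64435145e-01,1.23776269e-01
7.74106118e-02,2.47244112e-01,1.08623920e-01
8.13726689e-02,2.32302268e-01,9.57556020e-02
8.55375135e-02,2.19280273e-01,8.48402152e-02
8.99155246e-02,2.07896212e-01,7.55939515e-02
9.45176126e-02,1.97908873e-01,6.77735794e-02
9.93552463e-02,1.89111973e-01,6.11706750e-02
1.04440482e-01,1.81329190e-01,5.56066667e-02
1.09785991e-01,1.74409897e-01,5.09285811e-02
1.15405096e-01,1.68225506e-01,4.70053904e-02
1.21311800e-01,1.62666312e-01,4.37248791e-02
1.27520824e-01,1.57638798e-01,4.09909543e-02
1.34047639e-01,1.53063309e-01,3.87213398e-02
1.40908513e-01,1.48872066e-01,3.68455986e-02
1.48120542e-01,1.45007449e-01,3.53034371e-02
1.55701700e-01,1.41420534e-01,3.40432524e-02
1.63670879e-01,1.38069830e-01,3.30208861e-02
1.72047939e-01,1.34920198e-01,3.21985584e-02
1.80853757e-01,1.31941923e-01,3.15439526e-02
1.90110278e-01,1.29109917e-01,3.10294331e-02
1.99840569e-01,1.26403034e-01,3.06313735e-02
2.10068880e-01,1.23803487e-01,3.03295823e-02
2.20820699e-01,1.21296343e-01,3.01068104e-02
2.32122822e-01,1.18869090e-01,2.99483290e-02
2.44003413e-01,1.16511272e-01,2.98415683e-02
2.56492082e-01,1.14214170e-01,2.97758072e-02
2.69619950e-01,1.11970532e-01,2.97419083e-02
2.83419733e-01,1.09774343e-01,2.97320894e-02
2.97925822e-01,1.07620624e-01,2.97397291e-02
3.13174366e-01,1.05505268e-01,2.97591990e-02
3.29203366e-01,1.03424897e-01,2.97857203e-02
3.46052769e-01,1.01376737e-01,2.98152412e-02
3.63764564e-01,9.93585187e-02,2.98443316e-02
3.82382889e-01,9.73683895e-02,2.98700928e-02
4.01954145e-01,9.54048414e-02,2.98900812e-02
4.22527103e-01,9.34666499e-02,2.99022421e-02
4.44153034e-01,9.15528228e-02,2.99048540e-02
4.66885831e-01,8.96625589e-02,2.98964814e-02
4.90782146e-01,8.77952124e-02,2.98759339e-02
5.15901531e-01,8.59502651e-02,2.98422328e-02
5.42306584e-01,8.41273031e-02,2.97945820e-02
5.70063111e-01,8.23259978e-02,2.97323437e-02
5.99240281e-01,8.05460909e-02,2.96550188e-02
6.29910808e-01,7.87873825e-02,2.95622296e-02
6.62151125e-01,7.70497217e-02,2.94537056e-02
6.96041577e-01,7.53329986e-02,2.93292724e-02
7.31666622e-01,7.36371387e-02,2.91888412e-02
7.69115040e-01,7.19620982e-02,2.90324014e-02
8.08480157e-01,7.03078600e-02,2.88600133e-02
8.49860072e-01,6.86744312e-02,2.86718025e-02
8.93357910e-01,6.70618401e-02,2.84679551e-02
9.39082069e-01,6.54701342e-02,2.82487133e-02
9.87146497e-01,6.38993785e-02,2.80143715e-02
1.03767098e+00,6.23496536e-02,2.77652729e-02
1.09078142e+00,6.08210540e-02,2.75018064e-02
1.14661018e+00,5.93136862e-02,2.72244030e-02
1.20529638e+00,5.78276673e-02,2.69335333e-02
1.26698629e+00,5.63631230e-02,2.66297039e-02
1.33183362e+00,5.49201857e-02,2.63134549e-02
1.40000000e+00,5.34989929e-02,2.59853563e-02
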