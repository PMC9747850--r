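# element Fe (Z=26, A=55.845)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,1.69059580e+02,1.68883378e+02
1.05118235e-02,1.47917886e+02,1.47742179e+02
1.10498434e-02,1.29342426e+02,1.29167237e+02
1.16154003e-02,1.13031887e+02,1.12857239e+02
1.22099038e-02,9.87190907e+01,9.85450079e+01
1.28348354e-02,8.61672709e+01,8.59937779e+01
1.34917525e-02,7.51662644e+01,7.49933868e+01
1.41822921e-02,6.55294030e+01,6.53571673e+01
1.49081752e-02,5.70546091e+01,5.68830428e+01
1.56712107e-02,4.96513906e+01,4.94805220e+01
1.64733001e-02,4.31883857e+01,4.30182440e+01
1.73164423e-02,3.75503199e+01,3.73809353e+01
1.82027386e-02,3.26348759e+01,3.24662794e+01
1.91343975e-02,2.83515660e+01,2.81837896e+01
2.01137410e-02,2.46209581e+01,2.44540347e+01
2.11432096e-02,2.13733590e+01,2.12073223e+01
2.22253688e-02,1.85476502e+01,1.83825348e+01
2.33629154e-02,1.60902598e+01,1.59261012e+01
2.45586844e-02,1.39542540e+01,1.37910883e+01
2.58156556e-02,1.20985353e+01,1.19363997e+01
2.71369616e-02,1.04855291e+01,1.03244614e+01
2.85258951e-02,9.08382339e+00,8.92386200e+00
2.99859175e-02,7.86951204e+00,7.71069616e+00
3.15206672e-02,6.81411095e+00,6.65648032e+00
3.31339691e-02,5.89753684e+00,5.74113174e+00
3.48298436e-02,5.10590890e+00,4.95077010e+00
3.66125169e-02,4.42232676e+00,4.26849540e+00
3.84864316e-02,3.83215451e+00,3.67967205e+00
4.04562577e-02,3.32272000e+00,3.17162812e+00
4.25269041e-02,2.88305369e+00,2.73339420e+00
4.47035311e-02,2.50366196e+00,2.35547669e+00
4.69915629e-02,2.17633035e+00,2.02966107e+00
4.93967017e-02,1.89395282e+00,1.74884108e+00
5.19249410e-02,1.65038355e+00,1.50687060e+00
5.45825816e-02,1.44030843e+00,1.29843506e+00
5.73762465e-02,1.25913355e+00,1.11894002e+00
6.03128978e-02,1.10288860e+00,9.64414442e-01
6.33998537e-02,9.68142967e-01,8.31426899e-01
6.66448073e-02,8.51933156e-01,7.17012919e-01
7.00558453e-02,7.51699793e-01,6.18612023e-01
7.36414682e-02,6.65233085e-01,5.34013176e-01
7.74106118e-02,5.90625560e-01,4.61307529e-01
8.13726689e-02,5.26231147e-01,3.98847497e-01
8.55375135e-02,4.70629728e-01,3.45211322e-01
8.99155246e-02,4.22596469e-01,2.99172402e-01
9.45176126e-02,3.81075258e-01,2.59672742e-01
9.93552463e-02,3.45155734e-01,2.25799986e-01
1.04440482e-01,3.14053409e-01,1.96767544e-01
1.09785991e-01,2.87092471e-01,1.71897415e-01
1.15405096e-01,2.63690918e-01,1.50605324e-01
1.21311800e-01,2.43347704e-01,1.32387881e-01
1.27520824e-01,2.25631628e-01,1.16811482e-01
1.34047639e-01,2.10171730e-01,1.03502721e-01
1.40908513e-01,1.96648994e-01,9.21401057e-02
1.48120542e-01,1.84789187e-01,8.24469040e-02
1.55701700e-01,1.74356659e-01,7.41849703e-02
1.63670879e-01,1.65149008e-01,6.71494134e-02
1.72047939e-01,1.56992462e-01,6.11639968e-02
1.80853757e-01,1.49737896e-01,5.60771691e-02
1.90110278e-01,1.43257396e-01,5.17586409e-02
1.99840569e-01,1.37441299e-01,4.80964319e-02
2.10068880e-01,1.32195628e-01,4.49943248e-02
2.20820699e-01,1.27439894e-01,4.23696706e-02
2.32122822e-01,1.23105196e-01,4.01514966e-02
2.44003413e-01,1.19132576e-01,3.82788763e-02
2.56492082e-01,1.15471619e-01,3.66995244e-02
2.69619950e-01,1.12079228e-01,3.53685868e-02
2.83419733e-01,1.08918586e-01,3.42475986e-02
2.97925822e-01,1.05958254e-01,3.33035861e-02
3.13174366e-01,1.03171395e-01,3.25082944e-02
3.29203366e-01,1.00535115e-01,3.18375226e-02
3.46052769e-01,9.80298855e-02,3.12705510e-02
3.63764564e-01,9.56390605e-02,3.07896493e-02
3.82382889e-01,9.33484512e-02,3.03796535e-02
4.01954145e-01,9.11459690e-02,3.00276017e-02
4.22527103e-01,8.90213161e-02,2.97224221e-02
4.44153034e-01,8.69657230e-02,2.94546646e-02
4.66885831e-01,8.49717227e-02,2.92162706e-02
4.90782146e-01,8.30329589e-02,2.90003756e-02
5.15901531e-01,8.11440221e-02,2.88011406e-02
5.42306584e-01,7.93003100e-02,2.86136067e-02
5.70063111e-01,7.74979086e-02,2.84335717e-02
5.99240281e-01,7.57334912e-02,2.82574840e-02
6.29910808e-01,7.40042326e-02,2.80823523e-02
6.62151125e-01,7.23077358e-02,2.79056685e-02
6.96041577e-01,7.06419700e-02,2.77253414e-02
7.31666622e-01,6.90052183e-02,2.75396408e-02
7.69115040e-01,6.73960323e-02,2.73471492e-02
8.08480157e-01,6.58131943e-02,2.71467211e-02
8.49860072e-01,6.42556847e-02,2.69374476e-02
8.93357910e-01,6.27226540e-02,2.67186264e-02
9.39082069e-01,6.12133995e-02,2.64897363e-02
9.87146497e-01,5.97273442e-02,2.62504143e-02
1.03767098e+00,5.82640197e-02,2.60004370e-02
1.09078142e+00,5.68230505e-02,2.57397037e-02
1.14661018e+00,5.54041410e-02,2.54682214e-02
1.20529638e+00,5.40070638e-02,2.51860924e-02
1.26698629e+00,5.26316495e-02,2.48935028e-02
1.33183362e+00,5.12777772e-02,2.45907119e-02
1.40000000e+00,4.99453674e-02,2.42780438e-02
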