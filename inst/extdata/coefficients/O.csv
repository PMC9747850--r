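# element O (Z=8, A=15.999)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,5.54642548e+00,5.35718210e+00
1.05118235e-02,4.76595683e+00,4.57724599e+00
1.10498434e-02,4.09832122e+00,3.91016677e+00
1.16154003e-02,3.52732332e+00,3.33975002e+00
1.22099038e-02,3.03909953e+00,2.85213304e+00
1.28348354e-02,2.62171863e+00,2.43538554e+00
1.34917525e-02,2.26495658e+00,2.07928443e+00
1.41822921e-02,1.96005396e+00,1.77507125e+00
1.49081752e-02,1.69950766e+00,1.51524383e+00
1.56712107e-02,1.47689193e+00,1.29337742e+00
1.64733001e-02,1.28670477e+00,1.10397099e+00
1.73164423e-02,1.12423609e+00,9.42315418e-01
1.82027386e-02,9.85454476e-01,8.04380268e-01
1.91343975e-02,8.66910089e-01,6.86716676e-01
2.01137410e-02,7.65651347e-01,5.86374020e-01
2.11432096e-02,6.79153447e-01,5.00828443e-01
2.22253688e-02,6.05257076e-01,4.27921559e-01
2.33629154e-02,5.42115855e-01,3.65807897e-01
2.45586844e-02,4.88151299e-01,3.12909846e-01
2.58156556e-02,4.42014199e-01,2.67879041e-01
2.71369616e-02,4.02430561e-01,2.29442289e-01
2.85258951e-02,3.68378445e-01,1.96578404e-01
2.99859175e-02,3.39285253e-01,1.68715493e-01
3.15206672e-02,3.14401465e-01,1.45104677e-01
3.31339691e-02,2.93089805e-01,1.25109257e-01
3.48298436e-02,2.74808455e-01,1.08187918e-01
3.66125169e-02,2.59096772e-01,9.38804396e-02
3.84864316e-02,2.45563148e-01,8.17955468e-02
4.04562577e-02,2.33874678e-01,7.16005752e-02
4.25269041e-02,2.23748384e-01,6.30126832e-02
4.47035311e-02,2.14943746e-01,5.57913784e-02
4.69915629e-02,2.07256353e-01,4.97321626e-02
4.93967017e-02,2.00512505e-01,4.46611277e-02
5.19249410e-02,1.94564629e-01,4.04303614e-02
5.45825816e-02,1.89287372e-01,3.69140408e-02
5.73762465e-02,1.84574287e-01,3.40051116e-02
6.03128978e-02,1.80335014e-01,3.16124649e-02
6.33998537e-02,1.76492885e-01,2.96585384e-02
6.66448073e-02,1.72982885e-01,2.80772770e-02
7.00558453e-02,1.69749921e-01,2.68124003e-02
7.36414682e-02,1.66747350e-01,2.58159306e-02
7.74106118e-02,1.63935728e-01,2.50469427e-02
8.13726689e-02,1.61281744e-01,2.44705022e-02
8.55375135e-02,1.58757316e-01,2.40567640e-02
8.99155246e-02,1.56338820e-01,2.37802077e-02
9.45176126e-02,1.54006435e-01,2.36189882e-02
9.93552463e-02,1.51743586e-01,2.35543856e-02
1.04440482e-01,1.49536464e-01,2.35703384e-02
1.09785991e-01,1.47373625e-01,2.36530483e-02
1.15405096e-01,1.45245639e-01,2.37906449e-02
1.21311800e-01,1.43144799e-01,2.39729027e-02
1.27520824e-01,1.41064863e-01,2.41910001e-02
1.34047639e-01,1.39000838e-01,2.44373171e-02
1.40908513e-01,1.36948795e-01,2.47052627e-02
1.48120542e-01,1.34905707e-01,2.49891296e-02
1.55701700e-01,1.32869309e-01,2.52839706e-02
1.63670879e-01,1.30837984e-01,2.55854944e-02
1.72047939e-01,1.28810652e-01,2.58899769e-02
1.80853757e-01,1.26786689e-01,2.61941853e-02
1.90110278e-01,1.24765841e-01,2.64953145e-02
1.99840569e-01,1.22748161e-01,2.67909316e-02
2.10068880e-01,1.20733951e-01,2.70789293e-02
2.20820699e-01,1.18723708e-01,2.73574847e-02
2.32122822e-01,1.16718080e-01,2.76250250e-02
2.44003413e-01,1.14717833e-01,2.78801963e-02
2.56492082e-01,1.12723810e-01,2.81218375e-02
2.69619950e-01,1.10736909e-01,2.83489568e-02
2.83419733e-01,1.08758056e-01,2.85607111e-02
2.97925822e-01,1.06788187e-01,2.87563882e-02
3.13174366e-01,1.04828228e-01,2.89353909e-02
3.29203366e-01,1.02879084e-01,2.90972226e-02
3.46052769e-01,1.00941630e-01,2.92414750e-02
3.63764564e-01,9.90166969e-02,2.93678176e-02
3.82382889e-01,9.71050705e-02,2.94759877e-02
4.01954145e-01,9.52074857e-02,2.95657827e-02
4.22527103e-01,9.33246243e-02,2.96370528e-02
4.44153034e-01,9.14571143e-02,2.96896951e-02
4.66885831e-01,8.96055306e-02,2.97236491e-02
4.90782146e-01,8.77703963e-02,2.97388922e-02
5.15901531e-01,8.59521856e-02,2.97354372e-02
5.42306584e-01,8.41513268e-02,2.97133294e-02
5.70063111e-01,8.23682061e-02,2.96726454e-02
5.99240281e-01,8.06031717e-02,2.96134920e-02
6.29910808e-01,7.88565380e-02,2.95360054e-02
6.62151125e-01,7.71285900e-02,2.94403509e-02
6.96041577e-01,7.54195876e-02,2.93267236e-02
7.31666622e-01,7.37297694e-02,2.91953480e-02
7.69115040e-01,7.20593570e-02,2.90464787e-02
8.08480157e-01,7.04085582e-02,2.88804012e-02
8.49860072e-01,6.87775703e-02,2.86974316e-02
8.93357910e-01,6.71665828e-02,2.84979175e-02
9.39082069e-01,6.55757797e-02,2.82822378e-02
9.87146497e-01,6.40053414e-02,2.80508028e-02
1.03767098e+00,6.24554461e-02,2.78040540e-02
1.09078142e+00,6.09262710e-02,2.75424633e-02
1.14661018e+00,5.94179926e-02,2.72665325e-02
1.20529638e+00,5.79307869e-02,2.69767917e-02
1.26698629e+00,5.64648297e-02,2.66737985e-02
1.33183362e+00,5.50202958e-02,2.63581359e-02
1.40000000e+00,5.35973582e-02,2.60304106e-02
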