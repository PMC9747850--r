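# element Cl (Z=17, A=35.450)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,5.58144996e+01,5.56330081e+01
1.05118235e-02,4.83422067e+01,4.81612259e+01
1.10498434e-02,4.18547726e+01,4.16743255e+01
1.16154003e-02,3.62249196e+01,3.60450298e+01
1.22099038e-02,3.13414822e+01,3.11621743e+01
1.28348354e-02,2.70870440e+01,2.69083436e+01
1.34917525e-02,2.34046636e+01,2.32265971e+01
1.41822921e-02,2.02191762e+01,2.00417709e+01
1.49081752e-02,1.74644775e+01,1.72877616e+01
1.56712107e-02,1.50831274e+01,1.49071301e+01
1.64733001e-02,1.30252317e+01,1.28499831e+01
1.73164423e-02,1.12474652e+01,1.10729965e+01
1.82027386e-02,9.71222049e+00,9.53856356e+00
1.91343975e-02,8.38686426e+00,8.21405205e+00
2.01137410e-02,7.24308949e+00,7.07115583e+00
2.11432096e-02,6.25635047e+00,6.08533013e+00
2.22253688e-02,5.40537058e+00,5.23529919e+00
2.33629154e-02,4.67171335e+00,4.50262743e+00
2.45586844e-02,4.03940911e+00,3.87134601e+00
2.58156556e-02,3.49462980e+00,3.32762767e+00
2.71369616e-02,3.02463136e+00,2.85872914e+00
2.85258951e-02,2.61883526e+00,2.45407260e+00
2.99859175e-02,2.27000947e+00,2.10642670e+00
3.15206672e-02,1.97020703e+00,1.80784508e+00
3.31339691e-02,1.71257827e+00,1.55147865e+00
3.48298436e-02,1.49122075e+00,1.33142542e+00
3.66125169e-02,1.30104942e+00,1.14260078e+00
3.84864316e-02,1.13768456e+00,9.80625307e-01
4.04562577e-02,9.97354862e-01,8.41727932e-01
4.25269041e-02,8.76813735e-01,7.22662190e-01
4.47035311e-02,7.73267008e-01,6.20633939e-01
4.69915629e-02,6.84310515e-01,5.33238929e-01
4.93967017e-02,6.07876201e-01,4.58408905e-01
5.19249410e-02,5.42185614e-01,3.94365090e-01
5.45825816e-02,4.85709762e-01,3.39578043e-01
5.73762465e-02,4.37134497e-01,2.92733030e-01
6.03128978e-02,3.95330642e-01,2.52700158e-01
6.33998537e-02,3.59328245e-01,2.18508618e-01
6.66448073e-02,3.28294378e-01,1.89324484e-01
7.00558453e-02,3.01514005e-01,1.64431581e-01
7.36414682e-02,2.78373495e-01,1.43214996e-01
7.74106118e-02,2.58346418e-01,1.25146882e-01
8.13726689e-02,2.40981321e-01,1.09774226e-01
8.55375135e-02,2.25891188e-01,9.67083248e-02
8.99155246e-02,2.12744383e-01,8.56157199e-02
9.45176126e-02,2.01256842e-01,7.62104070e-02
9.93552463e-02,1.91185362e-01,6.82471279e-02
1.04440482e-01,1.82321828e-01,6.15156052e-02
1.09785991e-01,1.74488242e-01,5.58355854e-02
1.15405096e-01,1.67532458e-01,5.10525790e-02
1.21311800e-01,1.61324504e-01,4.70342007e-02
1.27520824e-01,1.55753429e-01,4.36670261e-02
1.34047639e-01,1.50724591e-01,4.08538919e-02
1.40908513e-01,1.46157322e-01,3.85115796e-02
1.48120542e-01,1.41982932e-01,3.65688264e-02
1.55701700e-01,1.38142980e-01,3.49646190e-02
1.63670879e-01,1.34587801e-01,3.36467300e-02
1.72047939e-01,1.31275237e-01,3.25704626e-02
1.80853757e-01,1.28169545e-01,3.16975742e-02
1.90110278e-01,1.25240461e-01,3.09953531e-02
1.99840569e-01,1.22462397e-01,3.04358273e-02
2.10068880e-01,1.19813753e-01,2.99950860e-02
2.20820699e-01,1.17276321e-01,2.96526981e-02
2.32122822e-01,1.14834783e-01,2.93912133e-02
2.44003413e-01,1.12476274e-01,2.91957351e-02
2.56492082e-01,1.10190007e-01,2.90535538e-02
2.69619950e-01,1.07966958e-01,2.89538325e-02
2.83419733e-01,1.05799589e-01,2.88873376e-02
2.97925822e-01,1.03681619e-01,2.88462079e-02
3.13174366e-01,1.01607824e-01,2.88237566e-02
3.29203366e-01,9.95738645e-02,2.88143013e-02
3.46052769e-01,9.75761477e-02,2.88130191e-02
3.63764564e-01,9.56116999e-02,2.88158215e-02
3.82382889e-01,9.36780664e-02,2.88192483e-02
4.01954145e-01,9.17732231e-02,2.88203764e-02
4.22527103e-01,8.98955038e-02,2.88167422e-02
4.44153034e-01,8.80435388e-02,2.88062751e-02
4.66885831e-01,8.62162037e-02,2.87872412e-02
4.90782146e-01,8.44125768e-02,2.87581954e-02
5.15901531e-01,8.26319040e-02,2.87179411e-02
5.42306584e-01,8.08735697e-02,2.86654955e-02
5.70063111e-01,7.91370733e-02,2.86000610e-02
5.99240281e-01,7.74220096e-02,2.85210009e-02
6.29910808e-01,7.57280532e-02,2.84278189e-02
6.62151125e-01,7.40549458e-02,2.83201420e-02
6.96041577e-01,7.24024859e-02,2.81977066e-02
7.31666622e-01,7.07705207e-02,2.80603460e-02
7.69115040e-01,6.91589388e-02,2.79079809e-02
8.08480157e-01,6.75676657e-02,2.77406109e-02
8.49860072e-01,6.59966583e-02,2.75583073e-02
8.93357910e-01,6.44459020e-02,2.73612067e-02
9.39082069e-01,6.29154071e-02,2.71495065e-02
9.87146497e-01,6.14052059e-02,2.69234596e-02
1.03767098e+00,5.99153505e-02,2.66833703e-02
1.09078142e+00,5.84459100e-02,2.64295907e-02
1.14661018e+00,5.69969689e-02,2.61625169e-02
1.20529638e+00,5.55686241e-02,2.58825858e-02
1.26698629e+00,5.41609836e-02,2.55902712e-02
1.33183362e+00,5.27741637e-02,2.52860811e-02
1.40000000e+00,5.14082871e-02,2.49705540e-02
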