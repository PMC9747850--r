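# element Ni (Z=28, A=58.693)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,2.07010272e+02,2.06829722e+02
1.05118235e-02,1.81568233e+02,1.81388192e+02
1.10498434e-02,1.59105714e+02,1.58926204e+02
1.16154003e-02,1.39290422e+02,1.39111466e+02
1.22099038e-02,1.21869327e+02,1.21690950e+02
1.28348354e-02,1.06562774e+02,1.06385002e+02
1.34917525e-02,9.31226037e+01,9.29454618e+01
1.41822921e-02,8.13287417e+01,8.11522576e+01
1.49081752e-02,7.09861404e+01,7.08103421e+01
1.56712107e-02,6.19220409e+01,6.17469575e+01
1.64733001e-02,5.39830497e+01,5.38087111e+01
1.73164423e-02,4.70131849e+01,4.68396222e+01
1.82027386e-02,4.09192403e+01,4.07464851e+01
1.91343975e-02,3.55999571e+01,3.54280422e+01
2.01137410e-02,3.09592077e+01,3.07881668e+01
2.11432096e-02,2.69124933e+01,2.67423610e+01
2.22253688e-02,2.33853219e+01,2.32161336e+01
2.33629154e-02,2.03128576e+01,2.01446497e+01
2.45586844e-02,1.76379681e+01,1.74707777e+01
2.58156556e-02,1.53103860e+01,1.51442511e+01
2.71369616e-02,1.32842732e+01,1.31192324e+01
2.85258951e-02,1.15210285e+01,1.13571214e+01
2.99859175e-02,9.99080171e+00,9.82806834e+00
3.15206672e-02,8.66328783e+00,8.50176895e+00
3.31339691e-02,7.51205718e+00,7.35179407e+00
3.48298436e-02,6.51406784e+00,6.35510226e+00
3.66125169e-02,5.64722680e+00,5.48960091e+00
3.84864316e-02,4.89258524e+00,4.73634152e+00
4.04562577e-02,4.24060400e+00,4.08578516e+00
4.25269041e-02,3.67741885e+00,3.52406774e+00
4.47035311e-02,3.19102047e+00,3.03917996e+00
4.69915629e-02,2.77100837e+00,2.62072123e+00
4.93967017e-02,2.40837723e+00,2.25968604e+00
5.19249410e-02,2.09533141e+00,1.94827845e+00
5.45825816e-02,1.82512393e+00,1.67975100e+00
5.73762465e-02,1.59191666e+00,1.44826500e+00
6.03128978e-02,1.39065906e+00,1.24876919e+00
6.33998537e-02,1.21698291e+00,1.07689449e+00
6.66448073e-02,1.06711102e+00,9.28862725e-01
7.00558453e-02,9.37778037e-01,8.01407416e-01
7.36414682e-02,8.26161796e-01,6.91705110e-01
7.74106118e-02,7.29823741e-01,5.97315846e-01
8.13726689e-02,6.46657338e-01,5.16131539e-01
8.55375135e-02,5.74843337e-01,4.46331258e-01
8.99155246e-02,5.12811012e-01,3.86342467e-01
9.45176126e-02,4.59204580e-01,3.34807451e-01
9.93552463e-02,4.12854117e-01,2.90554242e-01
1.04440482e-01,3.72750373e-01,2.52571439e-01
1.09785991e-01,3.38022961e-01,2.19986411e-01
1.15405096e-01,3.07921485e-01,1.92046430e-01
1.21311800e-01,2.81799201e-01,1.68102353e-01
1.27520824e-01,2.59098885e-01,1.47594493e-01
1.34047639e-01,2.39340601e-01,1.30040408e-01
1.40908513e-01,2.22111131e-01,1.15024341e-01
1.48120542e-01,2.07054826e-01,1.02188086e-01
1.55701700e-01,1.93865704e-01,9.12230988e-02
1.63670879e-01,1.82280612e-01,8.18636793e-02
1.72047939e-01,1.72073326e-01,7.38810781e-02
1.80853757e-01,1.63049449e-01,6.70784108e-02
1.90110278e-01,1.55042001e-01,6.12862632e-02
1.99840569e-01,1.47907619e-01,5.63588992e-02
2.10068880e-01,1.41523268e-01,5.21709867e-02
2.20820699e-01,1.35783407e-01,4.86147719e-02
2.32122822e-01,1.30597545e-01,4.55976423e-02
2.44003413e-01,1.25888127e-01,4.30400238e-02
2.56492082e-01,1.21588718e-01,4.08735669e-02
2.69619950e-01,1.17642431e-01,3.90395834e-02
2.83419733e-01,1.14000581e-01,3.74876981e-02
2.97925822e-01,1.10621513e-01,3.61746868e-02
3.13174366e-01,1.07469610e-01,3.50634756e-02
3.29203366e-01,1.04514421e-01,3.41222780e-02
3.46052769e-01,1.01729927e-01,3.33238524e-02
3.63764564e-01,9.90939019e-02,3.26448625e-02
3.82382889e-01,9.65873644e-02,3.20653271e-02
4.01954145e-01,9.41941093e-02,3.15681467e-02
4.22527103e-01,9.19003052e-02,3.11386965e-02
4.44153034e-01,8.96941492e-02,3.07644763e-02
4.66885831e-01,8.75655719e-02,3.04348105e-02
4.90782146e-01,8.55059846e-02,3.01405898e-02
5.15901531e-01,8.35080635e-02,2.98740501e-02
5.42306584e-01,8.15655652e-02,2.96285826e-02
5.70063111e-01,7.96731693e-02,2.93985716e-02
5.99240281e-01,7.78263441e-02,2.91792551e-02
6.29910808e-01,7.60212325e-02,2.89666058e-02
6.62151125e-01,7.42545539e-02,2.87572291e-02
6.96041577e-01,7.25235215e-02,2.85482764e-02
7.31666622e-01,7.08257714e-02,2.83373702e-02
7.69115040e-01,6.91593021e-02,2.81225407e-02
8.08480157e-01,6.75224230e-02,2.79021711e-02
8.49860072e-01,6.59137105e-02,2.76749515e-02
8.93357910e-01,6.43319704e-02,2.74398382e-02
9.39082069e-01,6.27762055e-02,2.71960201e-02
9.87146497e-01,6.12455879e-02,2.69428887e-02
1.03767098e+00,5.97394352e-02,2.66800128e-02
1.09078142e+00,5.82571902e-02,2.64071162e-02
1.14661018e+00,5.67984021e-02,2.61240587e-02
1.20529638e+00,5.53627121e-02,2.58308191e-02
1.26698629e+00,5.39498387e-02,2.55274804e-02
1.33183362e+00,5.25595668e-02,2.52142167e-02
1.40000000e+00,5.11917362e-02,2.48912816e-02
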