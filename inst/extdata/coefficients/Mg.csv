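# element Mg (Z=12, A=24.305)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,2.00534660e+01,1.98666090e+01
1.05118235e-02,1.72668856e+01,1.70805545e+01
1.10498434e-02,1.48666135e+01,1.46808318e+01
1.16154003e-02,1.27997187e+01,1.26145108e+01
1.22099038e-02,1.10204339e+01,1.08358252e+01
1.28348354e-02,9.48919804e+00,9.30521472e+00
1.34917525e-02,8.17182475e+00,7.98849404e+00
1.41822921e-02,7.03878164e+00,6.85613166e+00
1.49081752e-02,6.06456444e+00,5.88262429e+00
1.56712107e-02,5.22715446e+00,5.04595418e+00
1.64733001e-02,4.50754809e+00,4.32711868e+00
1.73164423e-02,3.88934908e+00,3.70972252e+00
1.82027386e-02,3.35841520e+00,3.17962444e+00
1.91343975e-02,2.90255222e+00,2.72463115e+00
2.01137410e-02,2.51124886e+00,2.33423233e+00
2.11432096e-02,2.17544741e+00,1.99937118e+00
2.22253688e-02,1.88734512e+00,1.71224591e+00
2.33629154e-02,1.64022251e+00,1.46613789e+00
2.45586844e-02,1.42829492e+00,1.25526337e+00
2.58156556e-02,1.24658340e+00,1.07464419e+00
2.71369616e-02,1.09079917e+00,9.19992377e-01
2.85258951e-02,9.57284435e-01,7.87650891e-01
2.99859175e-02,8.42884001e-01,6.74465223e-01
3.15206672e-02,7.44859905e-01,5.77698046e-01
3.31339691e-02,6.60861900e-01,4.94999683e-01
3.48298436e-02,5.88873081e-01,4.24353724e-01
3.66125169e-02,5.27163056e-01,3.64030196e-01
3.84864316e-02,4.74247646e-01,3.12545249e-01
4.04562577e-02,4.28854189e-01,2.68626455e-01
4.25269041e-02,3.89891690e-01,2.31182958e-01
4.47035311e-02,3.56425150e-01,1.99279785e-01
4.69915629e-02,3.27653484e-01,1.72115765e-01
4.93967017e-02,3.02890539e-01,1.49004537e-01
5.19249410e-02,2.81548780e-01,1.29358233e-01
5.45825816e-02,2.63125269e-01,1.12673453e-01
5.73762465e-02,2.47189625e-01,9.85192140e-02
6.03128978e-02,2.33373682e-01,8.65266096e-02
6.33998537e-02,2.21362606e-01,7.63799245e-02
6.66448073e-02,2.10887276e-01,6.78090109e-02
7.00558453e-02,2.01717744e-01,6.05827474e-02
7.36414682e-02,1.93657621e-01,5.45034278e-02
7.74106118e-02,1.86539267e-01,4.94019489e-02
8.13726689e-02,1.80219659e-01,4.51336859e-02
8.55375135e-02,1.74576858e-01,4.15749573e-02
8.99155246e-02,1.69506969e-01,3.86199972e-02
9.45176126e-02,1.64921547e-01,3.61783610e-02
9.93552463e-02,1.60745367e-01,3.41727060e-02
1.04440482e-01,1.56914511e-01,3.25368907e-02
1.09785991e-01,1.53374739e-01,3.12143500e-02
1.15405096e-01,1.50080081e-01,3.01567042e-02
1.21311800e-01,1.46991642e-01,2.93225712e-02
1.27520824e-01,1.44076567e-01,2.86765505e-02
1.34047639e-01,1.41307164e-01,2.81883551e-02
1.40908513e-01,1.38660148e-01,2.78320708e-02
1.48120542e-01,1.36115988e-01,2.75855226e-02
1.55701700e-01,1.33658360e-01,2.74297344e-02
1.63670879e-01,1.31273662e-01,2.73484674e-02
1.72047939e-01,1.28950613e-01,2.73278257e-02
1.80853757e-01,1.26679895e-01,2.73559204e-02
1.90110278e-01,1.24453861e-01,2.74225817e-02
1.99840569e-01,1.22266267e-01,2.75191130e-02
2.10068880e-01,1.20112060e-01,2.76380818e-02
2.20820699e-01,1.17987182e-01,2.77731393e-02
2.32122822e-01,1.15888407e-01,2.79188667e-02
2.44003413e-01,1.13813208e-01,2.80706439e-02
2.56492082e-01,1.11759629e-01,2.82245362e-02
2.69619950e-01,1.09726190e-01,2.83771975e-02
2.83419733e-01,1.07711797e-01,2.85257869e-02
2.97925822e-01,1.05715670e-01,2.86678974e-02
3.13174366e-01,1.03737279e-01,2.88014943e-02
3.29203366e-01,1.01776292e-01,2.89248623e-02
3.46052769e-01,9.98325352e-02,2.90365603e-02
3.63764564e-01,9.79059493e-02,2.91353824e-02
3.82382889e-01,9.59965657e-02,2.92203245e-02
4.01954145e-01,9.41044794e-02,2.92905560e-02
4.22527103e-01,9.22298298e-02,2.93453951e-02
4.44153034e-01,9.03727855e-02,2.93842889e-02
4.66885831e-01,8.85335322e-02,2.94067956e-02
4.90782146e-01,8.67122635e-02,2.94125700e-02
5.15901531e-01,8.49091748e-02,2.94013519e-02
5.42306584e-01,8.31244583e-02,2.93729553e-02
5.70063111e-01,8.13583006e-02,2.93272612e-02
5.99240281e-01,7.96108811e-02,2.92642106e-02
6.29910808e-01,7.78823714e-02,2.91837989e-02
6.62151125e-01,7.61729357e-02,2.90860726e-02
6.96041577e-01,7.44827318e-02,2.89711252e-02
7.31666622e-01,7.28119121e-02,2.88390952e-02
7.69115040e-01,7.11606251e-02,2.86901639e-02
8.08480157e-01,6.95290168e-02,2.85245537e-02
8.49860072e-01,6.79172322e-02,2.83425271e-02
8.93357910e-01,6.63254165e-02,2.81443853e-02
9.39082069e-01,6.47537159e-02,2.79304670e-02
9.87146497e-01,6.32022790e-02,2.77011478e-02
1.03767098e+00,6.16712566e-02,2.74568384e-02
1.09078142e+00,6.01608026e-02,2.71979839e-02
1.14661018e+00,5.86710737e-02,2.69250619e-02
1.20529638e+00,5.72022288e-02,2.66385812e-02
1.26698629e+00,5.57544290e-02,2.63390798e-02
1.33183362e+00,5.43278363e-02,2.60271227e-02
1.40000000e+00,5.29226130e-02,2.57033004e-02
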