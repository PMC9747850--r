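# element Ir (Z=77, A=192.217)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,1.01689018e+02,1.01537410e+02
1.05118235e-02,8.92551168e+01,8.91039353e+01
1.10498434e-02,7.83290756e+01,7.81783398e+01
1.16154003e-02,1.81229834e+02,1.81079564e+02
1.22099038e-02,1.58295550e+02,1.58145766e+02
1.28348354e-02,1.92674549e+02,1.92525272e+02
1.34917525e-02,1.94993065e+02,1.94844318e+02
1.41822921e-02,1.71818988e+02,1.71670794e+02
1.49081752e-02,1.51140095e+02,1.50992476e+02
1.56712107e-02,1.32893563e+02,1.32746545e+02
1.64733001e-02,1.16798655e+02,1.16652262e+02
1.73164423e-02,1.02599021e+02,1.02453279e+02
1.82027386e-02,9.00859126e+01,8.99408490e+01
1.91343975e-02,7.90674667e+01,7.89231088e+01
2.01137410e-02,6.93694536e+01,6.92258296e+01
2.11432096e-02,6.08373000e+01,6.06944389e+01
2.22253688e-02,5.33340600e+01,5.31919916e+01
2.33629154e-02,4.67366168e+01,4.65953716e+01
2.45586844e-02,4.09409719e+01,4.08005811e+01
2.58156556e-02,3.58519852e+01,3.57124807e+01
2.71369616e-02,3.13784625e+01,3.12398768e+01
2.85258951e-02,2.74432487e+01,2.73056149e+01
2.99859175e-02,2.39985161e+01,2.38618679e+01
3.15206672e-02,2.09837111e+01,2.08480827e+01
3.31339691e-02,1.83456814e+01,1.82111075e+01
3.48298436e-02,1.60377814e+01,1.59042971e+01
3.66125169e-02,1.40190840e+01,1.38867246e+01
3.84864316e-02,1.22536870e+01,1.21224882e+01
4.04562577e-02,1.07101028e+01,1.05801005e+01
4.25269041e-02,9.36072048e+00,9.23195064e+00
4.47035311e-02,8.18133368e+00,8.05383230e+00
4.69915629e-02,7.15072454e+00,7.02452754e+00
4.93967017e-02,6.24980779e+00,6.12495093e+00
5.19249410e-02,5.46223926e+00,5.33875802e+00
5.45825816e-02,4.77483317e+00,4.65276266e+00
5.73762465e-02,4.17451237e+00,4.05388722e+00
6.03128978e-02,3.64968075e+00,3.53053499e+00
6.33998537e-02,3.19208475e+00,3.07445168e+00
6.66448073e-02,2.79346318e+00,2.67737527e+00
7.00558453e-02,2.44620905e+00,2.33169783e+00
7.36414682e-02,2.14369462e+00,2.03079054e+00
7.61043888e-02,1.96594771e+00,1.85411893e+00
7.61196112e-02,9.33289644e+00,9.22107423e+00
7.74106118e-02,8.96024736e+00,8.84897969e+00
8.13726689e-02,7.90301884e+00,7.79341556e+00
8.55375135e-02,6.95156542e+00,6.84365307e+00
8.99155246e-02,6.11374875e+00,6.00755237e+00
9.45176126e-02,5.37625820e+00,5.27180120e+00
9.93552463e-02,4.72692605e+00,4.62423012e+00
1.04440482e-01,4.15260101e+00,4.05168605e+00
1.09785991e-01,3.64885541e+00,3.54973942e+00
1.15405096e-01,3.20706616e+00,3.10976519e+00
1.21311800e-01,2.81965488e+00,2.72418296e+00
1.27520824e-01,2.47996236e+00,2.38633146e+00
1.34047639e-01,2.18213800e+00,2.09035798e+00
1.40908513e-01,1.92104246e+00,1.83112105e+00
1.48120542e-01,1.69216189e+00,1.60410467e+00
1.55701700e-01,1.48946270e+00,1.40327310e+00
1.63670879e-01,1.31025639e+00,1.22593570e+00
1.72047939e-01,1.15410691e+00,1.07165430e+00
1.80853757e-01,1.01798909e+00,9.37401638e-01
1.90110278e-01,8.99279024e-01,8.20551777e-01
1.99840569e-01,7.95700375e-01,7.18826374e-01
2.10068880e-01,7.05277810e-01,6.30248172e-01
2.20820699e-01,6.26296825e-01,5.53100807e-01
2.32122822e-01,5.57268944e-01,4.85894024e-01
2.44003413e-01,4.96901629e-01,4.27333587e-01
2.56492082e-01,4.44072221e-01,3.76295232e-01
2.69619950e-01,3.97805393e-01,3.31802117e-01
2.83419733e-01,3.57253617e-01,2.93005297e-01
2.97925822e-01,3.21680251e-01,2.59166811e-01
3.13174366e-01,2.90444883e-01,2.29645025e-01
3.29203366e-01,2.62990635e-01,2.03881937e-01
3.46052769e-01,2.38833152e-01,1.81392167e-01
3.63764564e-01,2.17551063e-01,1.61753412e-01
3.82382889e-01,1.98777708e-01,1.44598172e-01
4.01954145e-01,1.82193956e-01,1.29606565e-01
4.22527103e-01,1.67521985e-01,1.16500104e-01
4.44153034e-01,1.54519877e-01,1.05036283e-01
4.66885831e-01,1.42976930e-01,9.50038924e-02
4.90782146e-01,1.32709587e-01,8.62189381e-02
5.15901531e-01,1.23557905e-01,7.85211068e-02
5.42306584e-01,1.15382483e-01,7.17706916e-02
5.70063111e-01,1.08061799e-01,6.58459226e-02
5.99240281e-01,1.01489895e-01,6.06406467e-02
6.29910808e-01,9.55743590e-02,5.60623110e-02
6.62151125e-01,9.02345826e-02,5.20302104e-02
6.96041577e-01,8.54002357e-02,4.84739627e-02
7.31666622e-01,8.10099452e-02,4.53321838e-02
7.69115040e-01,7.70101450e-02,4.25513341e-02
8.08480157e-01,7.33540744e-02,4.00847149e-02
8.49860072e-01,7.00009073e-02,3.78915956e-02
8.93357910e-01,6.69149939e-02,3.59364526e-02
9.39082069e-01,6.40651996e-02,3.41883079e-02
9.87146497e-01,6.14243307e-02,3.26201517e-02
1.03767098e+00,5.89686321e-02,3.12084399e-02
1.09078142e+00,5.66773507e-02,2.99326556e-02
1.14661018e+00,5.45323546e-02,2.87749273e-02
1.20529638e+00,5.25178000e-02,2.77196951e-02
1.26698629e+00,5.06198418e-02,2.67534197e-02
1.33183362e+00,4.88263802e-02,2.58643282e-02
1.40000000e+00,4.71268393e-02,2.50421922e-02
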