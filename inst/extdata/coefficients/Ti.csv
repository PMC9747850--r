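# element Ti (Z=22, A=47.867)
# mass attenuation / mass energy-absorption coefficients, cm^2/g
# incoherent: free-electron Klein-Nishina; photoabsorption: Cromer-Liberman (gemmi); coherent excluded; no fluorescence
energy_mev,mu_rho,mu_en_rho
1.00000000e-02,1.09238783e+02,1.09064839e+02
1.05118235e-02,9.50991171e+01,9.49256623e+01
1.10498434e-02,8.27460809e+01,8.25731375e+01
1.16154003e-02,7.19649093e+01,7.17925001e+01
1.22099038e-02,6.25610128e+01,6.23891614e+01
1.28348354e-02,5.43624173e+01,5.41911481e+01
1.34917525e-02,4.72181146e+01,4.70474528e+01
1.41822921e-02,4.09955685e+01,4.08255405e+01
1.49081752e-02,3.55785110e+01,3.54091437e+01
1.56712107e-02,3.08649935e+01,3.06963150e+01
1.64733001e-02,2.67656491e+01,2.65976882e+01
1.73164423e-02,2.32022357e+01,2.30350222e+01
1.82027386e-02,2.01062235e+01,1.99397881e+01
1.91343975e-02,1.74176396e+01,1.72520137e+01
2.01137410e-02,1.50840269e+01,1.49192430e+01
2.11432096e-02,1.30595252e+01,1.28956166e+01
2.22253688e-02,1.13023059e+01,1.11393069e+01
2.33629154e-02,9.77982447e+00,9.61776992e+00
2.45586844e-02,8.46226224e+00,8.30118797e+00
2.58156556e-02,7.32244293e+00,7.16238552e+00
2.71369616e-02,6.33419630e+00,6.17519306e+00
2.85258951e-02,5.47609528e+00,5.31818420e+00
2.99859175e-02,4.73595812e+00,4.57917787e+00
3.15206672e-02,4.09770820e+00,3.94209800e+00
3.31339691e-02,3.54743723e+00,3.39303686e+00
3.48298436e-02,3.07311571e+00,2.91996541e+00
3.66125169e-02,2.66434168e+00,2.51248206e+00
3.84864316e-02,2.31212265e+00,2.16159464e+00
4.04562577e-02,2.00868662e+00,1.85953138e+00
4.25269041e-02,1.74731808e+00,1.59957686e+00
4.47035311e-02,1.52221585e+00,1.37592997e+00
4.69915629e-02,1.32836992e+00,1.18358058e+00
4.93967017e-02,1.16145464e+00,1.01820288e+00
5.19249410e-02,1.01773621e+00,8.76062743e-01
5.45825816e-02,8.93992604e-01,7.53937711e-01
5.73762465e-02,7.87444117e-01,6.49047525e-01
6.03128978e-02,6.95693332e-01,5.58994078e-01
6.33998537e-02,6.16673108e-01,4.81709408e-01
6.66448073e-02,5.48601585e-01,4.15410697e-01
7.00558453e-02,4.89943254e-01,3.58561345e-01
7.36414682e-02,4.39375286e-01,3.09837297e-01
7.74106118e-02,3.95758420e-01,2.68097931e-01
8.13726689e-02,3.58111790e-01,2.32360888e-01
8.55375135e-02,3.25591173e-01,2.01780325e-01
8.99155246e-02,2.97470190e-01,1.75628119e-01
9.45176126e-02,2.73124072e-01,1.53277641e-01
9.93552463e-02,2.52015632e-01,1.34189733e-01
1.04440482e-01,2.33683162e-01,1.17900616e-01
1.09785991e-01,2.17729975e-01,1.04011440e-01
1.15405096e-01,2.03815391e-01,9.21792799e-02
1.21311800e-01,1.91646950e-01,8.21093624e-02
1.27520824e-01,1.80973700e-01,7.35483638e-02
1.34047639e-01,1.71580405e-01,6.62786341e-02
1.40908513e-01,1.63282557e-01,6.01132180e-02
1.48120542e-01,1.55922068e-01,5.48915649e-02
1.55701700e-01,1.49363565e-01,5.04758337e-02
1.63670879e-01,1.43491189e-01,4.67477111e-02
1.72047939e-01,1.38205849e-01,4.36056713e-02
1.80853757e-01,1.33422842e-01,4.09626180e-02
1.90110278e-01,1.29069819e-01,3.87438552e-02
1.99840569e-01,1.25085024e-01,3.68853406e-02
2.10068880e-01,1.21415778e-01,3.53321836e-02
2.20820699e-01,1.18017184e-01,3.40373536e-02
2.32122822e-01,1.14851003e-01,3.29605686e-02
2.44003413e-01,1.11884692e-01,3.20673400e-02
2.56492082e-01,1.09090579e-01,3.13281517e-02
2.69619950e-01,1.06445151e-01,3.07177535e-02
2.83419733e-01,1.03928442e-01,3.02145552e-02
2.97925822e-01,1.01523516e-01,2.98001048e-02
3.13174366e-01,9.92160125e-02,2.94586409e-02
3.29203366e-01,9.69937642e-02,2.91767082e-02
3.46052769e-01,9.48464694e-02,2.89428271e-02
3.63764564e-01,9.27654102e-02,2.87472107e-02
3.82382889e-01,9.07432125e-02,2.85815216e-02
4.01954145e-01,8.87736419e-02,2.84386634e-02
4.22527103e-01,8.68514291e-02,2.83126026e-02
4.44153034e-01,8.49721222e-02,2.81982157e-02
4.66885831e-01,8.31319611e-02,2.80911582e-02
4.90782146e-01,8.13277706e-02,2.79877537e-02
5.15901531e-01,7.95568711e-02,2.78848980e-02
5.42306584e-01,7.78170015e-02,2.77799784e-02
5.70063111e-01,7.61062559e-02,2.76708044e-02
5.99240281e-01,7.44230292e-02,2.75555489e-02
6.29910808e-01,7.27659717e-02,2.74326982e-02
6.62151125e-01,7.11339508e-02,2.73010099e-02
6.96041577e-01,6.95260188e-02,2.71594769e-02
7.31666622e-01,6.79413862e-02,2.70072965e-02
7.69115040e-01,6.63793988e-02,2.68438449e-02
8.08480157e-01,6.48395184e-02,2.66686553e-02
8.49860072e-01,6.33213066e-02,2.64813986e-02
8.93357910e-01,6.18244115e-02,2.62818679e-02
9.39082069e-01,6.03485551e-02,2.60699647e-02
9.87146497e-01,5.88935237e-02,2.58456866e-02
1.03767098e+00,5.74591592e-02,2.56091172e-02
1.09078142e+00,5.60453510e-02,2.53604171e-02
1.14661018e+00,5.46520296e-02,2.50998156e-02
1.20529638e+00,5.32791603e-02,2.48276036e-02
1.26698629e+00,5.19267379e-02,2.45441268e-02
1.33183362e+00,5.05947819e-02,2.42497799e-02
1.40000000e+00,4.92833318e-02,2.39450009e-02
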