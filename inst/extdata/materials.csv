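# Material library: elemental mass compositions (percent) and densities (g/cm3)
# for the digital-phantom tissue/implant set and the HDR source hardware.
# Values are stored as published; the loader renormalises each composition to
# unit mass-fraction sum (the cartilage and stainless-steel rows sum to 99.7%
# and 99.0% as printed) and, unless strict mode is requested, corrects the
# titanium row (printed Al 6 / Ti 9 / V 4, an evident Ti-6Al-4V misprint) to
# Ti 90%. The trace element printed as "Z" in tissue rows is zinc.
material,density,element,percent
titanium,4.42,Al,6
titanium,4.42,Ti,9
titanium,4.42,V,4
lung,0.26,H,10.1278
lung,0.26,C,10.231
lung,0.26,N,2.865
lung,0.26,O,75.7072
lung,0.26,Na,0.184
lung,0.26,Mg,0.073
lung,0.26,P,0.08
lung,0.26,Si,0.225
lung,0.26,Cl,0.266
lung,0.26,K,0.194
lung,0.26,Ca,0.009
lung,0.26,Fe,0.037
lung,0.26,Zn,0.001
muscle,1.05,H,10.0637
muscle,1.05,C,10.783
muscle,1.05,N,2.768
muscle,1.05,O,75.4773
muscle,1.05,Na,0.075
muscle,1.05,Mg,0.019
muscle,1.05,P,0.18
muscle,1.05,Si,0.241
muscle,1.05,Cl,0.079
muscle,1.05,K,0.302
muscle,1.05,Ca,0.003
muscle,1.05,Fe,0.004
muscle,1.05,Zn,0.005
bone,1.92,H,4.7234
bone,1.92,C,14.433
bone,1.92,N,4.199
bone,1.92,O,44.6096
bone,1.92,Mg,0.22
bone,1.92,P,10.497
bone,1.92,Si,0.315
bone,1.92,K,20.993
bone,1.92,Zn,0.01
adipose,0.92,H,11.9477
adipose,0.92,C,63.724
adipose,0.92,N,0.797
adipose,0.92,O,23.2333
adipose,0.92,Na,0.05
adipose,0.92,Mg,0.002
adipose,0.92,P,0.016
adipose,0.92,Si,0.073
adipose,0.92,Cl,0.119
adipose,0.92,K,0.032
adipose,0.92,Ca,0.002
adipose,0.92,Fe,0.002
adipose,0.92,Zn,0.002
cartilage,1.1,H,9.6
cartilage,1.1,C,9.6
cartilage,1.1,N,2.2
cartilage,1.1,O,74.4
cartilage,1.1,Na,0.5
cartilage,1.1,P,2.2
cartilage,1.1,Si,0.9
cartilage,1.1,Cl,0.3
stainless_steel,8,C,0.08
stainless_steel,8,P,0.045
stainless_steel,8,Cr,19
stainless_steel,8,Mn,2
stainless_steel,8,Fe,68.375
stainless_steel,8,Ni,9.5
peek,1.31,H,4.1954
peek,1.31,C,79.1557
peek,1.31,O,16.6489
pmma,1.19,H,8.0542
pmma,1.19,C,59.984
pmma,1.19,O,31.9618
water,1,H,11.1894
water,1,O,88.8106
air,0.0012,H,0.0732
air,0.0012,C,0.0123
air,0.0012,N,75.0325
air,0.0012,O,23.6077
air,0.0012,Ar,1.2743
vacuum,0.000001,H,100
iridium_seed,22.42,Ir,100
steel_304,5.6,C,0.08
steel_304,5.6,N,0.1
steel_304,5.6,Si,0.75
steel_304,5.6,P,0.045
steel_304,5.6,S,0.03
steel_304,5.6,Cr,19
steel_304,5.6,Mn,2
steel_304,5.6,Fe,68.745
steel_304,5.6,Ni,9.25
steel_316l,8.03,C,0.03
steel_316l,8.03,N,0.1
steel_316l,8.03,Si,0.75
steel_316l,8.03,P,0.045
steel_316l,8.03,S,0.03
steel_316l,8.03,Cr,17
steel_316l,8.03,Mn,2
steel_316l,8.03,Fe,65.545
steel_316l,8.03,Ni,12
steel_316l,8.03,Mo,2.5
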