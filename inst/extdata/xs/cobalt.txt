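# photon interaction coefficients: metallic cobalt
# density_g_cm3 8.9
# composition Co:1
# Z-scaling from the NIST iron anchors
# fractions are branch probabilities (photoelectric, incoherent, coherent, pair); they sum to 1 per row
energy_MeV mu_rho f_photo f_incoh f_coh f_pair mu_en_rho
0.01 191.3864967 0.9875064932 0.0009233020451 0.01157020476 0 153.7194365
0.015 63.99640344 0.9812735345 0.002711596997 0.01601486854 0 54.96105466
0.02 28.76823438 0.9734487342 0.005926827079 0.02062443869 0 25.35829693
0.03 9.136899275 0.9519023056 0.01804225259 0.03005544182 0 8.121593384
0.04 4.040381423 0.9211327019 0.03951990279 0.03934739532 0 3.522624448
0.05 2.168814539 0.8805967608 0.07143133991 0.04797189933 0 1.820200623
0.06 1.326197177 0.8310063467 0.1135110459 0.05548260743 0 1.055127281
0.08 0.6449203889 0.7126502456 0.2212993843 0.06605037007 0 0.445960288
0.1 0.396038284 0.58633271 0.3432766089 0.07039068114 0 0.232362087
0.15 0.2022637981 0.3310981381 0.6051106596 0.06379120227 0 0.08192519218
0.2 0.147536536 0.1892231342 0.7601482838 0.05062858197 0 0.04868091562
0.3 0.1093767329 0.0768139497 0.891578051 0.03160799929 0 0.0334016852
0.4 0.09306766608 0.0396858554 0.9388091404 0.02150500418 0 0.03005604993
0.5 0.08312097732 0.02441468574 0.9598274016 0.01575791264 0 0.02876343761
0.6 0.07602193656 0.01699997933 0.9708150066 0.01218501403 0 0.02796714972
0.8 0.06603398353 0.01017153824 0.9817073803 0.008121081434 0 0.02674098744
1 0.05906793386 0.007519063559 0.9865393755 0.005941560967 0 0.02563875919
1.022 0.05841325933 0.007239328031 0.9869958726 0.005764799355 0 0.02550907961
1.1 0.05625669346 0.006683781915 0.9881059909 0.005205135427 5.091767375e-06 0.02507685366
1.17 0.05451252229 0.00667546542 0.988517179 0.004777524503 2.983103267e-05 0.02472137939
1.25 0.05270583635 0.007124047947 0.9884256767 0.004357773001 9.250235655e-05 0.02434730017
1.33 0.05110165721 0.008613285245 0.9871966225 0.003994838581 0.0001952536882 0.02397073086
1.35 0.05072344769 0.009032687823 0.9868280483 0.003912095181 0.0002271686853 0.02388118894
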