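# photon interaction coefficients: liquid water
# density_g_cm3 0.998
# composition H:0.111898 O:0.888102
# totals and mu_en anchored to the NIST compilation for liquid water
# fractions are branch probabilities (photoelectric, incoherent, coherent, pair); they sum to 1 per row
energy_MeV mu_rho f_photo f_incoh f_coh f_pair mu_en_rho
0.01 5.329 0.8941456523 0.04017598403 0.06567836367 0 4.944
0.015 1.673 0.7774995188 0.125672983 0.09682749828 0 1.374
0.02 0.8096 0.628999204 0.255165596 0.1158352001 0 0.5503
0.03 0.3756 0.3526720577 0.5317667333 0.115561209 0 0.1557
0.04 0.2683 0.185278984 0.7210654941 0.09365552186 0 0.06947
0.05 0.2269 0.1002801497 0.8272444638 0.07247538653 0 0.04223
0.06 0.2059 0.0576929862 0.8858231598 0.05648385403 0 0.0319
0.08 0.1837 0.02203527643 0.9413135477 0.03665117589 0 0.02597
0.1 0.1707 0.009236785429 0.9649504498 0.02581276474 0 0.02546
0.15 0.1505 0.001137769192 0.9853116425 0.01355058835 0 0.02764
0.2 0.137 0 0.9913861197 0.008613880298 0 0.02967
0.3 0.1186 0 0.9953964562 0.004603543833 0 0.03192
0.4 0.1061 0 0.9970206267 0.002979373284 0 0.03279
0.5 0.09687 0 0.9978628503 0.002137149743 0 0.03299
0.6 0.08956 0 0.9983653018 0.001634698203 0 0.03284
0.8 0.07865 0.0002845493772 0.9986377495 0.00107770114 0 0.03206
1 0.07072 0.000869570196 0.9983460511 0.000784378701 0 0.03103
1.022 0.06995210764 0.0006585296546 0.9985806002 0.0007608701354 0 0.03089263962
1.1 0.06741799519 0.0003270334408 0.9989851994 0.0006865088003 1.258376883e-06 0.03043287867
1.17 0.0653632873 0.0005048333749 0.9988580296 0.0006297686261 7.368421948e-06 0.03005250654
1.25 0.06323 0.001159048353 0.9982439776 0.0005741373994 2.283663616e-05 0.02965
1.33 0.06123344663 0.001248870379 0.9981759293 0.0005269400658 4.826022407e-05 0.02919410321
1.35 0.06076256303 0.00133395081 0.9980937083 0.0005161759902 5.616489529e-05 0.02908546519
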