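# photon interaction coefficients: air, 40% humidity (TG-43U1 composition)
# density_g_cm3 0.001196
# composition Ar:0.012743 C:0.000123 H:0.000732 N:0.750325 O:0.236077
# dry-air NIST anchors mixed with 0.65% water vapour by mass
# fractions are branch probabilities (photoelectric, incoherent, coherent, pair); they sum to 1 per row
energy_MeV mu_rho f_photo f_incoh f_coh f_pair mu_en_rho
0.01 5.1213585 0.8947013684 0.03764936749 0.06764926414 0 4.743313
0.015 1.6143835 0.7833825966 0.1172902127 0.09932719072 0 1.33426
0.02 0.77810605 0.6415940156 0.2391026805 0.1193033039 0 0.5389741
0.03 0.3539417 0.3703962556 0.5082128424 0.121390902 0 0.153713
0.04 0.2486287 0.1991890696 0.7007687814 0.100042149 0 0.06833741
0.05 0.20812285 0.1095554598 0.8122303628 0.07821417742 0 0.040988125
0.06 0.1876196 0.06314110288 0.8754992754 0.0613596217 0 0.030419685
0.08 0.16631375 0.02356062022 0.9363666319 0.04007274783 0 0.02408235
0.1 0.1542079 0.009743728012 0.9619722197 0.02828405231 0 0.023264365
0.15 0.13569685 0.0009514367849 0.9841719149 0.01487664831 0 0.02497742
0.2 0.12338905 0 0.9905402968 0.009459703208 0 0.026739175
0.3 0.10677735 0 0.9949424113 0.005057588699 0 0.0287408
0.4 0.095558965 0 0.9967262449 0.00327375514 0 0.02951145
0.5 0.087183375 0 0.9976514906 0.002348509369 0 0.029681645
0.6 0.080608565 0 0.998203544 0.001796456006 0 0.029551515
0.8 0.070791415 2.054892608e-06 0.9988132022 0.001184742902 0 0.02884106
1 0.06362641 6.282360229e-06 0.9991309048 0.0008628128607 0 0.02791041
1.022 0.06293809171 4.757468557e-06 0.9991584626 0.0008367799516 0 0.02778790419
1.1 0.06066638 2.362290334e-06 0.9992414789 0.0007547566314 1.402214853e-06 0.02737782948
1.17 0.05882419959 3.646189825e-06 0.9992956425 0.0006925015712 8.209721524e-06 0.0270385244
1.25 0.05691134 0.0005128815379 0.9988302545 0.0006314230312 2.544090652e-05 0.026679435
1.33 0.05511346687 0.0005893565868 0.9987773535 0.0005795253076 5.376459607e-05 0.026268129
1.35 0.05468944567 0.0006710030972 0.9986987367 0.0005676891231 6.257107203e-05 0.02617011927
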