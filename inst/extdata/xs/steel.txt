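# photon interaction coefficients: stainless steel AISI 316L
# density_g_cm3 8.02
# composition Cr:0.17 Fe:0.655 Mn:0.02 Mo:0.025 Ni:0.12 Si:0.01
# elemental Z-scaling from the NIST iron anchors
# fractions are branch probabilities (photoelectric, incoherent, coherent, pair); they sum to 1 per row
energy_MeV mu_rho f_photo f_incoh f_coh f_pair mu_en_rho
0.01 185.0882304 0.9873936757 0.0009704489399 0.0116358754 0 148.6508643
0.015 61.89762683 0.9810463958 0.002849726075 0.0161038781 0 53.15378574
0.02 27.83009411 0.9730373474 0.006227549564 0.02073510307 0 24.52858377
0.03 8.844903707 0.9508587305 0.01894492496 0.03019634454 0 7.860902689
0.04 3.915764717 0.9190642417 0.04144938081 0.03948637747 0 3.413482904
0.05 2.105452387 0.8771461599 0.07479321308 0.04806062699 0 1.76685858
0.06 1.290269987 0.8259423523 0.1185938129 0.05546383486 0 1.026563881
0.08 0.6309279403 0.7044021577 0.2299338733 0.06566396897 0 0.4364650598
0.1 0.3898462158 0.5759779552 0.3544740613 0.06954798346 0 0.2289364448
0.15 0.201715073 0.3210365182 0.6167526338 0.062210848 0 0.08184085334
0.2 0.1482575054 0.1820853551 0.7689137305 0.04900091448 0 0.04900267528
0.3 0.1106110623 0.07344874369 0.8961529828 0.03039827348 0 0.03382082381
0.4 0.09433023825 0.0378618237 0.9415027735 0.02063540278 0 0.03049086911
0.5 0.08433240393 0.0232694003 0.9616249163 0.01510568335 0 0.02920198189
0.6 0.07716972077 0.01619415473 0.9721312036 0.0116746417 0 0.02840406749
0.8 0.06706506526 0.00968446588 0.9825385621 0.007776972054 0 0.02716795422
1 0.06000365016 0.007157407716 0.9871540604 0.005688531861 0 0.02605154147
1.022 0.05933986664 0.006890980504 0.987589839 0.005519180496 0 0.02592013098
1.1 0.05715201076 0.006361841581 0.9886501193 0.004983107414 4.931705469e-06 0.0254816342
1.17 0.05538108314 0.006353810734 0.9890436428 0.004573653743 2.889275862e-05 0.0251204158
1.25 0.05354530442 0.006780817292 0.9889577512 0.004171838123 8.959339707e-05 0.02473970913
1.33 0.05191245173 0.008198797606 0.9877874583 0.003824619254 0.0001891248429 0.02435521945
1.35 0.05152732014 0.008598171464 0.987436318 0.0037454685 0.0002200419898 0.02426371961
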