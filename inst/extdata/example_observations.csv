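species_id,population_id,study_id,stage,temperature_c,development_time_d
species_A,pop_1,study_1,egg_to_adult,15,20.484
species_A,pop_1,study_1,egg_to_adult,15,19.979
species_A,pop_1,study_1,egg_to_adult,15,21.292
species_A,pop_1,study_1,egg_to_adult,15,21.153
species_A,pop_1,study_1,egg_to_adult,15,19.1
species_A,pop_1,study_1,egg_to_adult,15,20.776
species_A,pop_1,study_1,egg_to_adult,15,18.994
species_A,pop_1,study_1,egg_to_adult,15,19.512
species_A,pop_1,study_1,egg_to_adult,15,20.037
species_A,pop_1,study_1,egg_to_adult,15,20.837
species_A,pop_1,study_1,egg_to_adult,20,10.168
species_A,pop_1,study_1,egg_to_adult,20,10.07
species_A,pop_1,study_1,egg_to_adult,20,10.317
species_A,pop_1,study_1,egg_to_adult,20,10.051
species_A,pop_1,study_1,egg_to_adult,20,10.235
species_A,pop_1,study_1,egg_to_adult,20,9.998
species_A,pop_1,study_1,egg_to_adult,20,10.045
species_A,pop_1,study_1,egg_to_adult,20,9.826
species_A,pop_1,study_1,egg_to_adult,20,10.12
species_A,pop_1,study_1,egg_to_adult,20,10.133
species_A,pop_1,study_1,egg_to_adult,25,6.728
species_A,pop_1,study_1,egg_to_adult,25,6.668
species_A,pop_1,study_1,egg_to_adult,25,6.706
species_A,pop_1,study_1,egg_to_adult,25,6.635
species_A,pop_1,study_1,egg_to_adult,25,6.66
species_A,pop_1,study_1,egg_to_adult,25,6.666
species_A,pop_1,study_1,egg_to_adult,25,6.683
species_A,pop_1,study_1,egg_to_adult,25,6.735
species_A,pop_1,study_1,egg_to_adult,25,6.686
species_A,pop_1,study_1,egg_to_adult,25,6.755
species_A,pop_1,study_1,egg_to_adult,30,5.056
species_A,pop_1,study_1,egg_to_adult,30,5.047
species_A,pop_1,study_1,egg_to_adult,30,4.966
species_A,pop_1,study_1,egg_to_adult,30,5.08
species_A,pop_1,study_1,egg_to_adult,30,5.044
species_A,pop_1,study_1,egg_to_adult,30,4.976
species_A,pop_1,study_1,egg_to_adult,30,5.009
species_A,pop_1,study_1,egg_to_adult,30,4.924
species_A,pop_1,study_1,egg_to_adult,30,5.031
species_A,pop_1,study_1,egg_to_adult,30,5.017
species_B,pop_1,study_1,egg_to_adult,15,178.244
species_B,pop_1,study_1,egg_to_adult,15,85.282
species_B,pop_1,study_1,egg_to_adult,15,150.197
species_B,pop_1,study_1,egg_to_adult,15,148.557
species_B,pop_1,study_1,egg_to_adult,15,218.525
species_B,pop_1,study_1,egg_to_adult,15,124.582
species_B,pop_1,study_1,egg_to_adult,15,125.933
species_B,pop_1,study_1,egg_to_adult,15,136.707
species_B,pop_1,study_1,egg_to_adult,15,119.639
species_B,pop_1,study_1,egg_to_adult,15,106.073
species_B,pop_1,study_1,egg_to_adult,20,46.945
species_B,pop_1,study_1,egg_to_adult,20,49.336
species_B,pop_1,study_1,egg_to_adult,20,46.953
species_B,pop_1,study_1,egg_to_adult,20,43.704
species_B,pop_1,study_1,egg_to_adult,20,44.341
species_B,pop_1,study_1,egg_to_adult,20,46.62
species_B,pop_1,study_1,egg_to_adult,20,39.628
species_B,pop_1,study_1,egg_to_adult,20,42.484
species_B,pop_1,study_1,egg_to_adult,20,41.892
species_B,pop_1,study_1,egg_to_adult,20,44.902
species_B,pop_1,study_1,egg_to_adult,25,26.603
species_B,pop_1,study_1,egg_to_adult,25,24.297
species_B,pop_1,study_1,egg_to_adult,25,25.532
species_B,pop_1,study_1,egg_to_adult,25,27.369
species_B,pop_1,study_1,egg_to_adult,25,28.496
species_B,pop_1,study_1,egg_to_adult,25,27.316
species_B,pop_1,study_1,egg_to_adult,25,27.215
species_B,pop_1,study_1,egg_to_adult,25,26.734
species_B,pop_1,study_1,egg_to_adult,25,26.713
species_B,pop_1,study_1,egg_to_adult,25,26.408
species_B,pop_1,study_1,egg_to_adult,30,18.948
species_B,pop_1,study_1,egg_to_adult,30,17.994
species_B,pop_1,study_1,egg_to_adult,30,19.862
species_B,pop_1,study_1,egg_to_adult,30,20.289
species_B,pop_1,study_1,egg_to_adult,30,19.73
species_B,pop_1,study_1,egg_to_adult,30,19.818
species_B,pop_1,study_1,egg_to_adult,30,19.239
species_B,pop_1,study_1,egg_to_adult,30,19.814
species_B,pop_1,study_1,egg_to_adult,30,18.859
species_B,pop_1,study_1,egg_to_adult,30,20.235
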