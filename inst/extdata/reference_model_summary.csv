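season,day_type,hour,r2,adjusted_r2,cv_adjusted_r2,rmse,cv_rmse
heating,working,0,0.955,0.951,0.947,19.79,29.39
heating,working,8,0.675,0.644,0.671,43.68,52.64
heating,working,18,0.829,0.818,0.800,45.48,27.33
heating,non_working,0,0.803,0.777,0.783,44.71,55.42
heating,non_working,8,0.732,0.706,0.698,42.75,14.52
heating,non_working,18,0.892,0.886,0.880,50.76,32.19
non_heating,working,0,0.668,0.628,0.592,5.08,9.55
non_heating,working,8,0.567,0.510,0.466,8.24,4.84
non_heating,working,18,0.354,0.312,0.299,7.72,7.92
non_heating,non_working,0,0.468,0.434,0.435,5.64,6.51
non_heating,non_working,8,0.635,0.598,0.605,7.87,9.23
non_heating,non_working,18,0.593,0.567,0.574,7.71,6.62
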