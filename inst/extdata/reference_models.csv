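season,day_type,hour,label,name,coefficient,t,sig,vif,partial_r2
heating,working,0,Intercept,(Intercept),-673.896,-15.482,0.000,NA,NA
heating,working,0,Relative humidity,relative_humidity,13.277,19.098,0.000,1.683,0.867
heating,working,0,Sports and leisure_2500,sports_leisure_2500,0.121,7.653,0.000,1.145,0.073
heating,working,0,Elevation,elevation,0.114,3.249,0.003,1.729,0.015
heating,working,8,Intercept,(Intercept),-813.746,-6.303,0.000,NA,NA
heating,working,8,Relative humidity,relative_humidity,13.137,7.280,0.000,1.521,0.608
heating,working,8,Primary road_1500,primary_road_1500,0.001,2.451,0.020,1.334,0.035
heating,working,8,Elevation,elevation,0.139,1.750,0.090,1.805,0.032
heating,working,18,Intercept,(Intercept),-384.327,-7.126,0.000,NA,NA
heating,working,18,Relative humidity,relative_humidity,13.117,11.583,0.000,2.987,0.549
heating,working,18,Temperature,temperature,46.992,7.126,0.000,2.987,0.280
heating,non_working,0,Intercept,(Intercept),-531.070,-6.734,0.000,NA,NA
heating,non_working,0,Relative humidity,relative_humidity,10.770,8.755,0.000,1.055,0.574
heating,non_working,0,Shopping places_2500,shopping_2500,1.814,5.122,0.000,4.116,0.143
heating,non_working,0,Financial banks_3000,financial_banks_3000,-0.122,-2.897,0.007,4.020,0.058
heating,non_working,0,Woodland_1300,woodland_1300,4.649e-05,2.058,0.048,1.145,0.028
heating,non_working,8,Intercept,(Intercept),-303.577,-4.439,0.000,NA,NA
heating,non_working,8,Relative humidity,relative_humidity,6.838,7.460,0.000,1.053,0.620
heating,non_working,8,Catering services_900,catering_900,-0.402,-3.131,0.004,1.124,0.055
heating,non_working,8,Grassland_800,grassland_800,-2.017e-04,-2.543,0.016,1.088,0.056
heating,non_working,18,Intercept,(Intercept),-499.405,-9.598,0.000,NA,NA
heating,non_working,18,Relative humidity,relative_humidity,14.742,15.132,0.000,1.010,0.824
heating,non_working,18,Shopping places_3000,shopping_3000,0.604,4.486,0.000,1.010,0.068
non_heating,working,0,Intercept,(Intercept),-130.226,-3.097,0.005,NA,NA
non_heating,working,0,Residential housing_500,residential_housing_500,0.296,3.296,0.003,1.230,0.412
non_heating,working,0,Temperature,temperature,6.581,3.860,0.001,1.079,0.193
non_heating,working,0,Grassland_3000,grassland_3000,-3.780e-06,-2.179,0.039,1.147,0.063
non_heating,working,8,Intercept,(Intercept),36.019,14.212,0.000,NA,NA
non_heating,working,8,Secondary road_300,secondary_road_300,0.009,4.374,0.000,1.908,0.363
non_heating,working,8,Financial banks_3000,financial_banks_3000,-0.023,-3.168,0.004,3.397,0.082
non_heating,working,8,Government agencies_300,government_300,0.294,2.099,0.044,2.050,0.065
non_heating,working,8,Life services_300,life_services_300,1.148,3.706,0.001,1.425,0.058
non_heating,working,18,Intercept,(Intercept),40.454,20.623,0.000,NA,NA
non_heating,working,18,Residential housing_300,residential_housing_300,0.665,2.634,0.013,1.114,0.257
non_heating,working,18,Scenic spots_3000,scenic_spots_3000,0.024,2.157,0.039,1.114,0.097
non_heating,non_working,0,Intercept,(Intercept),-32.405,-1.142,0.262,NA,NA
non_heating,non_working,0,Residential housing_2500,residential_housing_2500,0.009,2.382,0.023,1.738,0.398
non_heating,non_working,0,Temperature,temperature,2.553,2.041,0.050,1.738,0.069
non_heating,non_working,8,Intercept,(Intercept),-55.293,-1.501,0.144,NA,NA
non_heating,non_working,8,Medical care_300,medical_care_300,1.154,3.411,0.002,1.330,0.456
non_heating,non_working,8,Public facilities_2000,public_facilities_2000,0.036,2.883,0.007,1.185,0.116
non_heating,non_working,8,Relative humidity,relative_humidity,1.049,2.283,0.030,1.188,0.063
non_heating,non_working,18,Intercept,(Intercept),25.358,9.394,0.000,NA,NA
non_heating,non_working,18,Science and education places_500,science_education_500,0.188,3.192,0.003,1.710,0.510
non_heating,non_working,18,Primary road_2500,primary_road_2500,5.723e-05,2.559,0.015,1.710,0.083
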