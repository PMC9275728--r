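name,depth_m,temperature_C,salinity_g_kg,pressure_MPa,density_kg_m3,viscosity_mPa_s,surface_tension_mN_m,sound_speed_m_s,gamma_N2,gamma_O2,thermal_diffusivity_N2_1e9_m2_s,thermal_diffusivity_O2_1e9_m2_s
warm_surface,0,20.0,35.0,0.101325,1028,1.077,73.52,1522,1.401,1.397,21000,21210
cold_surface,0,1.50,35.0,0.101325,1027,1.812,76.01,1456,1.402,1.400,18620,18780
depth_1000m,1000,1.50,35.0,10.19,1032,1.812,76.01,1473,1.612,1.668,191.4,172.0
depth_2000m,2000,1.50,35.0,20.33,1036,1.812,76.01,1490,1.738,1.897,114.3,92.64
depth_3500m,3500,1.50,35.0,35.62,1043,1.812,76.01,1516,1.760,1.950,95.38,74.87
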