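quantity,heart,value
delta_p_kpa,A,1.5
delta_p_kpa,B,3.9
delta_p_kpa,C,0.78
delta_p_kpa,D,2.6
delta_p_sd_kpa,A,0.04
delta_p_sd_kpa,B,0.4
delta_p_sd_kpa,C,0.04
delta_p_sd_kpa,D,0.3
wss_mode_pa,A,0.003
wss_mode_pa,B,0.47
wss_mode_pa,C,0.23
wss_mode_pa,D,0.25
wss_median_pa,A,0.36
wss_median_pa,B,0.32
wss_median_pa,C,0.51
wss_median_pa,D,0.55
vortex_surface_m2,A,36.8e-3
vortex_surface_m2,B,61.3e-3
vortex_surface_m2,C,40e-3
vortex_surface_m2,D,54.6e-3
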