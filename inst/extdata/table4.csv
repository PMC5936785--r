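thickness_m,sigma_kg_m2,quantity,value
1e-2,7,delta_p_kpa,1.46
1e-2,20,delta_p_kpa,1.45
1e-2,40,delta_p_kpa,1.45
1e-2,70,delta_p_kpa,1.44
1.2e-2,7,delta_p_kpa,1.56
1.2e-2,20,delta_p_kpa,1.5
1.2e-2,40,delta_p_kpa,1.47
1.2e-2,70,delta_p_kpa,1.45
1e-2,7,wss_median_pa,1.3
1e-2,20,wss_median_pa,1.26
1e-2,40,wss_median_pa,1.11
1e-2,70,wss_median_pa,1.1
1.2e-2,7,wss_median_pa,1.27
1.2e-2,20,wss_median_pa,1.32
1.2e-2,40,wss_median_pa,1.2
1.2e-2,70,wss_median_pa,1.18
1e-2,7,vortex_surface_m2,38.5e-3
1e-2,20,vortex_surface_m2,36.4e-3
1e-2,40,vortex_surface_m2,32e-3
1e-2,70,vortex_surface_m2,31.4e-3
1.2e-2,7,vortex_surface_m2,36.3e-3
1.2e-2,20,vortex_surface_m2,36.8e-3
1.2e-2,40,vortex_surface_m2,35.7e-3
1.2e-2,70,vortex_surface_m2,32.9e-3
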