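quantity,heart,geometry,value
area_inlet_m2,A,,6e-4
area_inlet_m2,B,,10.2e-4
area_inlet_m2,C,,5.7e-4
area_inlet_m2,D,,9.4e-4
area_inlet_m2,E,,13.9e-4
area_outlet_m2,A,,2.5e-4
area_outlet_m2,B,,2.4e-4
area_outlet_m2,C,,3e-4
area_outlet_m2,D,,1.8e-4
area_outlet_m2,E,,4.9e-4
alpha_deg,A,,49
alpha_deg,B,,72.2
alpha_deg,C,,58.8
alpha_deg,D,,43.3
alpha_deg,E,,73.7
d_m,A,,2.1e-2
d_m,B,,1.9e-2
d_m,C,,2.3e-2
d_m,D,,2.3e-2
d_m,E,,2.3e-2
trabeculae_pct,A,,21.4
trabeculae_pct,B,,26.6
trabeculae_pct,C,,19.6
trabeculae_pct,D,,21.3
trabeculae_pct,E,,10.9
mesh_elements,A,smoothed,3012240
mesh_elements,A,detailed,2329175
mesh_elements,B,smoothed,3545080
mesh_elements,B,detailed,5525858
mesh_elements,C,smoothed,1773680
mesh_elements,C,detailed,5039205
mesh_elements,D,smoothed,1588160
mesh_elements,D,detailed,3251790
mesh_elements,E,smoothed,2583680
mesh_elements,E,detailed,4272960
mesh_points,A,smoothed,562926
mesh_points,A,detailed,476951
mesh_points,B,smoothed,632642
mesh_points,B,detailed,1140117
mesh_points,C,smoothed,333305
mesh_points,C,detailed,1038890
mesh_points,D,smoothed,204189
mesh_points,D,detailed,671442
mesh_points,E,smoothed,541204
mesh_points,E,detailed,764903
reynolds_inlet,A,,6004
reynolds_inlet,B,,4605
reynolds_inlet,C,,4477
reynolds_inlet,D,,5764
reynolds_inlet,E,,7009
delta_p_kpa,A,smoothed,1.3
delta_p_kpa,A,detailed,1.5
delta_p_kpa,B,smoothed,3.8
delta_p_kpa,B,detailed,4.1
delta_p_kpa,C,smoothed,0.7
delta_p_kpa,C,detailed,0.8
delta_p_kpa,D,smoothed,2.2
delta_p_kpa,D,detailed,4.9
delta_p_kpa,E,smoothed,2.3
delta_p_kpa,E,detailed,2.5
delta_p_sd_kpa,A,smoothed,0.1
delta_p_sd_kpa,A,detailed,0.1
delta_p_sd_kpa,B,smoothed,0.04
delta_p_sd_kpa,B,detailed,0.1
delta_p_sd_kpa,C,smoothed,0.06
delta_p_sd_kpa,C,detailed,0.05
delta_p_sd_kpa,D,smoothed,0.1
delta_p_sd_kpa,D,detailed,0.2
delta_p_sd_kpa,E,smoothed,
delta_p_sd_kpa,E,detailed,0.1
delta_p_diff_kpa,A,,0.2
delta_p_diff_kpa,B,,0.3
delta_p_diff_kpa,C,,0.1
delta_p_diff_kpa,D,,2.7
delta_p_diff_kpa,E,,0.2
wss_mode_pa,A,smoothed,0.35
wss_mode_pa,A,detailed,0.05
wss_mode_pa,B,smoothed,0.06
wss_mode_pa,B,detailed,0.05
wss_mode_pa,C,smoothed,0.75
wss_mode_pa,C,detailed,0.05
wss_mode_pa,D,smoothed,0.45
wss_mode_pa,D,detailed,0.05
wss_mode_pa,E,smoothed,0.15
wss_mode_pa,E,detailed,0.25
wss_median_pa,A,smoothed,0.51
wss_median_pa,A,detailed,0.39
wss_median_pa,B,smoothed,1.02
wss_median_pa,B,detailed,0.34
wss_median_pa,C,smoothed,1.23
wss_median_pa,C,detailed,0.67
wss_median_pa,D,smoothed,0.63
wss_median_pa,D,detailed,0.66
wss_median_pa,E,smoothed,0.84
wss_median_pa,E,detailed,0.52
vortex_surface_m2,A,smoothed,29.1e-3
vortex_surface_m2,A,detailed,35.6e-3
vortex_surface_m2,B,smoothed,33.8e-3
vortex_surface_m2,B,detailed,60.4e-3
vortex_surface_m2,C,smoothed,20.4e-3
vortex_surface_m2,C,detailed,37.7e-3
vortex_surface_m2,D,smoothed,45e-3
vortex_surface_m2,D,detailed,48.4e-3
vortex_surface_m2,E,smoothed,29.4e-3
vortex_surface_m2,E,detailed,35.3e-3
cores,A,smoothed,144
cores,A,detailed,96
cores,B,smoothed,144
cores,B,detailed,240
cores,C,smoothed,96
cores,C,detailed,240
cores,D,smoothed,96
cores,D,detailed,144
cores,E,smoothed,144
cores,E,detailed,192
ci_time_hhmm,A,smoothed,63:47
ci_time_hhmm,A,detailed,254:50
ci_time_hhmm,B,smoothed,91:13
ci_time_hhmm,B,detailed,110:10
ci_time_hhmm,C,smoothed,41:43
ci_time_hhmm,C,detailed,134:18
ci_time_hhmm,D,smoothed,18:17
ci_time_hhmm,D,detailed,419:47
ci_time_hhmm,E,smoothed,154:15
ci_time_hhmm,E,detailed,113:37
ci_dt_s,A,smoothed,9.85e-5
ci_dt_s,A,detailed,7.74e-5
ci_dt_s,B,smoothed,5.78e-5
ci_dt_s,B,detailed,6.68e-6
ci_dt_s,C,smoothed,7.17e-5
ci_dt_s,C,detailed,6.90e-5
ci_dt_s,D,smoothed,1.90e-4
ci_dt_s,D,detailed,5.51e-5
ci_dt_s,E,smoothed,1.35e-4
ci_dt_s,E,detailed,9.42e-5
ti_time_hhmm,A,smoothed,81:25
ti_time_hhmm,A,detailed,167:52
ti_time_hhmm,B,smoothed,335:12
ti_time_hhmm,B,detailed,340:18
ti_time_hhmm,C,smoothed,336:33
ti_time_hhmm,C,detailed,53:50
ti_time_hhmm,D,smoothed,265:20
ti_time_hhmm,D,detailed,213:53
ti_time_hhmm,E,smoothed,17:20
ti_time_hhmm,E,detailed,120:46
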