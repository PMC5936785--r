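geometry,instant,vortex_surface_m2
smoothed,1,9.4e-3
smoothed,2,16.7e-3
smoothed,3,17.4e-3
smoothed,4,25.5e-3
smoothed,5,22.5e-3
smoothed,6,23.7e-3
detailed,1,14.9e-3
detailed,2,18.1e-3
detailed,3,24.4e-3
detailed,4,29.2e-3
detailed,5,25.9e-3
detailed,6,26.6e-3
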