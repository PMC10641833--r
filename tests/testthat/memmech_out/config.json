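{"topology":null,"topology_dialect":"fixture","trajectory":"/none","trajectory_dialect":"fixture","pressure_csv":null,"series_csv":null,"n_per_leaflet":null,"species":null,"tail":"SN1","analyses":"apl","uneven_frames":500,"uneven_seed":1,"tmg_bin_width":1,"contacts_cutoff":11,"neighbors_cutoff":15,"diffusion_window":null,"ks_lag":null,"voronoi_leaflet":"upper","voronoi_frame":1,"out_dir":"memmech_out"}
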