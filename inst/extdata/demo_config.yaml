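geometry.lv_radius: 15.0
geometry.lv_length: 30.0
geometry.lv_wall: 10.5
geometry.rv_wall: 3.0
geometry.rv_gap: 4.0
geometry.edge_length: 2.5
protocol.quiescent_ms: 1000.0
protocol.cl_ms: 600.0
protocol.n_beats: 3.0
fit.r_tol_um: 0.05
fit.ecf_step: 0.05
fit.r_min_um: 9.6
fit.r_max_um: 17.8
tissue.r_ref_um: 15.45
tissue.ecv_ref: 0.258
tissue.ecf_ref: 0.0
engine: eikonal
seed: 1.0
output_dir: '.'
log_level: info
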