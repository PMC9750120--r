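# Example configuration: 600 kb chromosome, cohesin-like symmetric extrusion,
# impermeable boundaries with alternating 100/200 kb spacing.
chain_length_kb: 600
monomer_size_kb: 2
lef_density_kb: 60          # one bound LEF per 60 kb
velocity_kb_per_min: 100
unbind_rate_per_min: 0.05   # 20 min residence time
extrusion_mode: symmetric
collision_mode: impenetrable
rebind_mode: uniform
sim_time_min: 100
snapshot_interval_min: 1
equilibration_time_min: 5
n_replicates: 2
hic_bin_kb: 10
seed: 77
alternating_gaps_kb: [100, 200]
# boundaries may also be listed inline or read from a BED-like file:
# boundaries:
#   - {position_kb: 100, orientation: blocks_both, permeability: 0}
# boundaries_file: boundaries.bed
# reference_map: reference.cool     # enables the Comparison stage
# grid:                             # enables grid sweeps (run_grid / CLI grid)
#   lef_density_kb: [30, 60, 120]
#   velocity_kb_per_min: [25, 100, 400]
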