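schema: 1
model: single2patch
m: [0, 0.001, 0.1]
V_S: [5]
"N": [1000]
replicates: 2
base_seed: 7
scale: 0.05
n_flank_per_side: 5
final_only: true
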