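# Demo config for `ictalrank localize` / run_localize(), to be used on the
# session written by demo-simulate.yaml.
session: demo/session.json
output: demo/out
measure: auto      # DI first, GC fallback
p0: 10
p1: 5
reps: 50           # package default is 200; reduced for a quick demo
alpha: 0.85
block_length: 10
guard: 120
seed: 1001
di: {m: 2, k: 4, thin: 2, n_centers: 96}
gc: {order: 2}
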