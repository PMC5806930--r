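# Demo config for `ictalrank simulate` / run_simulate(): a 6x6 grid with a
# planted center source, tripled outgoing coupling during three seizures.
n_rows: 6
n_cols: 6
fs: 500
duration: 1300
source_node: "3C"
source_gain: 3
seizure_intervals:
  - [300, 360]
  - [700, 760]
  - [1100, 1160]
seed: 1
output: demo/session
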