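# Example run configuration for the fateflow command line.
# Stages read and write under `out`; `seed` is the global seed from
# which each stage derives its own stream.
data:
  expression: fixture/expression.tsv
  metadata: fixture/metadata.tsv
out: out
seed: 1
fixtures:
  form: bistable
  n_initial: 500
  n_per_snapshot: 500
process:
  k: 5
growth:
  mode: signature
  birth_genes: fixture/geneset_cycle.txt
  death_genes: fixture/geneset_apoptosis.txt
  dt_real: 1
train:
  epochs: 200
  hidden: 64
  eval_every: 100
  pretrain_steps: 50
evaluate:
  held_out_time: 1
  n_sim: 1000
fate:
  fate_A: right
  fate_B: left
  n_traj: 2000
screen:
  tf_list: fixture/geneset_axis.txt
  target_fate: right
  z: 5
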