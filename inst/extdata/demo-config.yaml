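# Demo pipeline configuration: a synthetic cohort small enough to run the
# full simulate -> embed -> encode -> fit -> evaluate -> interpret chain in a
# few CPU minutes.
n_codes: 200
n_groups: 20
n_patients: 300
n_pairs: 500
d: 4
D: 20
sparsity: 0.2
noise: 0.05
embed_method: sgns
embed_epochs: 10
embed_negatives: 5
pe: multiplicative
models:
  - s_ltr
  - p_ltr
  - lr
  - svm
  - nb
  - rf
k: 10
test_ratio: 0.2
max_steps: 800
lr: 0.01
lambda: 0.001
grid: false
seeds:
  cohort: 1
  embedding: 2
  fit: 3
  cv: 4
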