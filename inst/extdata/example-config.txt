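# Example run configuration for the desk-scale preset.
# Flat key = value; sections are cosmetic; unknown keys are rejected.

[cohort]
n_ids = 20
reps_per_cell = 8
protocol = age_based
image_size = 64
augment_train = false

[training]
preset = fe_net_tiny
lr = 0.02
momentum = 0.9
weight_decay = 0.0001
batch_size = 32
epochs = 20
alpha = 0.5
beta = 1
seed = 1
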