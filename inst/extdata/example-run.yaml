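# Example run configuration for the scattergap CLI. Flags given on the
# command line override these values.
size: 256
n: 50
epochs: 30
lr_step: 12
batch_size: 2
model: msdnet
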