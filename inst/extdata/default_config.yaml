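# Default run: coupled replication-removal with strong centripetal bias,
# corneal radius R = 100 (R_total = 101 with a one-cell limbal ring),
# local interaction radius m = 5, replicative lifespan 60, equipotent limbus.
model_class: coupled
bias: 0.95
m: 5
rls: 60
R_total: 101
limbal_width: 1
stem_model: equipotent
seed: 1
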