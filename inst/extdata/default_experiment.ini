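# Default two-system (apo-like vs holo-like) pulling experiment.
# Units: kJ/mol, nm, ps, K throughout.

[landscape]
# shared geometry; the bound-well depth is a template value that
# calibrateDepth() adjusts per system to hit the targets below
bounds = -0.15 0.55
thresholds = 0.12 0.25
bound_center = 0.02
bound_depth = 10
bound_halfwidth = 0.05
bound_softness = 0.015
unbound_center = 0.33
unbound_depth = 12
unbound_halfwidth = 0.06
unbound_softness = 0.015

[protocol]
# reference steered protocol slowed 8x (velocity in nm/ps)
spring_constant = 39000
lambda0 = 0
lambda1 = 0.35
velocity = 2.1875e-05
time_step = 0.01
temperature = 300
diffusion = 0.001
record_every = 8000

[analysis]
stride = 1
direction = breaking

[bootstrap]
n_resamples = 200
seed = 42

[experiment]
# true breaking free energies the two systems are calibrated to
target_apo = -2.5
target_holo = 1.9
n_replicas = 512
seed_apo = 1000001
seed_holo = 2000001
write_colvar = false
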