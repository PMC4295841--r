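# Reference model configuration: BCM with synaptic scaling, feed-forward,
# logistic IO curve, structural parameters of the rate model.
[structural]
ln_p_build = -16
rho = 0.125
a = 2.0
q = 1.3333333333333333
P = 12

[rule]
kind = bcm_scaling
mu = 0.2
theta = 0.08
kappa = 9
v_tss = 0.1

[neuron]
io = logistic
r0 = 0      # feed-forward system
r1 = 0

[point]
v_j = 0.656
v_i_S0 = 0.2975

[rng]
seed = 1
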