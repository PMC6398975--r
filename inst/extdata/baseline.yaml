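# Baseline parameterization (Table-1 symbols); absent keys keep defaults.
p_c: 0.95          # probability of Cas9 cutting per susceptible site
p_n: 0             # probability of NHEJ conditional on cutting
n_guides: 3        # multiplexed homing gRNAs
p_nf: 1            # per-mutation probability of gene non-functionality
placement: "noncoding"
p_y: 1             # Y-shredding efficiency
xo_fertility: 0.6  # litter-size multiplier for XO females
p_x_xo: 0.66       # X:O transmission bias of XO mothers
k: 10000           # carrying capacity
litter_mean: 6
r_max: 7.76        # maximum annual population growth rate
f_max: 1           # maximum female mates per male per cycle
inoculum_size: 100
years: 10
replicates: 1000
seed: 1
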