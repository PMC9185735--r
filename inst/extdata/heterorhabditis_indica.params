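# Ecoclimatic model parameters for Heterorhabditis indica
# (literature-derived; temperatures in degrees C, soil moisture as a
# fraction of field capacity, stress rates per unit exceedance per week)

# temperature index
dv0 = 18
dv1 = 25
dv2 = 30
dv3 = 33

# moisture index
sm0 = 0.08
sm1 = 0.1
sm2 = 0.7
sm3 = 1.7

# cold stress
ttcs = 11
thcs = 0.0002

# heat stress
tths = 36
thhs = 0.0003

# dry stress
smds = 0.08
hds = 0.001

# wet stress
smws = 1.7
hws = 0.003

species_name = Heterorhabditis indica
notes = Warm-adapted entomopathogenic nematode; infective-juvenile survival parameters
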