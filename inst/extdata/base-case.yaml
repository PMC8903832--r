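# Prototypical smoothing experiment: undulated inoculum in the
# intermediate porous medium, standard nutrient.
lambda: 800.0      # undulation wavelength (um)
xi: 1.7            # porous-medium preset label (um)
A0: 300.0          # undulation amplitude (um)
sensing: log
c0: 10000.0        # initial nutrient (uM) = 10 mM
preset: desk
t_max: 21600.0     # 6 hr (s)
output_interval: 300.0
c_plus: 30.0
signal: yes
dx: 20.0
dt: 0.05
Lx: 6000.0
x_frac: 0.2
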