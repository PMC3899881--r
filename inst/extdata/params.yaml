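# Physical constants of the oxygen transport model (defaults shown).
D: 2.0e-9        # oxygen diffusion coefficient, m^2 s^-1 (close to water)
p_o: 100         # surface oxygen partial pressure, mmHg
Omega: 3.0318e7  # Henry's-law conversion constant, mmHg kg m^-3
rho_O2: 1.331    # density of O2 gas, kg m^-3
rho_T: 1000      # tissue density, kg m^-3 (water)
M_O2: 0.032      # molar mass of O2, kg mol^-1
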