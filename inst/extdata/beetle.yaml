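# Ladybird-beetle hairy-pad model parameters.
# Tensions in mN/m, angles in degrees (receding), lengths in um,
# volumes in fl (= um^3).
fluids:
  gamma_fa: 27.5    # tarsal fluid - air (n-hexadecane-like)
  gamma_wa: 72.8    # water - air
  gamma_fw: 53.5    # tarsal fluid - water
substrates:
  glass:            # untreated glass, hydrophilic
    theta_fa: 6
    theta_wa: 20
  PFOTS:            # fluorosilanized glass, hydrophobic
    theta_fa: 56
    theta_wa: 93
pad:
  pad_diameter: 200
  hair_diameter: 2
  hair_length: 50
  n_hairs: 2000
  phi_f: 2          # fluid volume per hair via D_h / (2 s_f)
bubble:
  phi_b: 1.5        # bubble volume via D_p / (2 s_b)
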