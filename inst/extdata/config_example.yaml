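# Annotated run configuration for cyanoH2.
#
# Every block is optional: omitted keys take the laboratory defaults (the
# fitted parameter values of the Cyanothece sp. ATCC 51142 flat-plate
# experiments). Unknown keys are rejected. A parameter may be written as a
# bare number (the canonical unit below is assumed) or, to make the unit
# explicit, as {value: ..., unit: "..."}; the unit string must then match
# the canonical unit exactly.

model: heterotrophic          # heterotrophic | autotrophic
seed: 1                       # drives all stochastic paths (synth, multistart)

optics:
  tau_c: {value: 0.126, unit: "m^2 g^-1"}   # cell absorption cross-section
  alpha_g: 0.0067                           # gas hold-up fraction (unit "1")
  d_b: {value: 0.002, unit: "m"}            # mean bubble diameter

light:
  I0: {value: 92, unit: "umol m^-2 s^-1"}   # incident flux per surface
  L: {value: 0.025, unit: "m"}              # light path (reactor width)
  n_surfaces: 1                             # 1 or 2 illuminated faces
  n_steps: 20                               # base trapezoid intervals
  adaptive: true                            # refine with optical depth

autotrophic:
  mu_max_a: {value: 0.255, unit: "h^-1"}
  mu_d_a: {value: 0.00227, unit: "L h^-1 g^-1"}
  ks: {value: 165, unit: "umol m^-2 s^-1"}  # light saturation (growth)
  ki: {value: 457, unit: "umol m^-2 s^-1"}  # photoinhibition (growth)

heterotrophic:
  mu_max_h: {value: 0.332, unit: "h^-1"}
  mu_d_h: {value: 0.00716, unit: "L h^-1 g^-1"}
  kq: 0.165                                 # minimum normalized N quota
  K_N: {value: 50.0, unit: "mg L^-1"}
  K_C: {value: 0.0, unit: "mmol L^-1"}      # 0: glycerol never limiting
  Y_NX: {value: 492.7, unit: "mg g^-1"}
  Y_qX: {value: 0.0317, unit: "g^-1"}
  Y_HX: {value: 14.20, unit: "mL g^-1 h^-1"}
  Y_OX: {value: 81.02, unit: "L g^-1"}
  Y_Od: {value: 486.03, unit: "L g^-2"}
  Y_CX: {value: 20.454, unit: "mmol g^-1"}
  Y_C: {value: 0.0301, unit: "mmol g^-1 h^-1"}
  ks: {value: 165, unit: "umol m^-2 s^-1"}
  ki: {value: 457, unit: "umol m^-2 s^-1"}
  ks_H2: {value: 140, unit: "umol m^-2 s^-1"}
  ki_H2: {value: 457, unit: "umol m^-2 s^-1"}

initial_state:                # nutrient-replete laboratory batch
  X: {value: 0.2, unit: "g L^-1"}
  N: {value: 500, unit: "mg L^-1"}
  q: 1.0                      # full quota at inoculation
  C: {value: 50, unit: "mmol L^-1"}
  O2: {value: 0, unit: "L L^-1"}
  H2: {value: 0, unit: "mL L^-1"}

times:
  from: {value: 0, unit: "h"}
  to: {value: 150, unit: "h"}
  by: {value: 1, unit: "h"}

solver:
  method: lsoda               # lsoda | radau | rk4 | collocation
  rtol: 1.0e-8
  atol: 1.0e-10
  dt: 1.0e-3                  # rk4 step (h)
  n_sub: 8                    # collocation elements per output interval
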