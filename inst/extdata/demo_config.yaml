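# Demonstration pipeline configuration: a one-tenth-scale synthetic cohort
# over six study years. All values are illustrative fixtures, not estimates
# from any real dataset; see ?sim_params for the meaning of each parameter.
output_dir: rtimort-demo
seed: 1
simulation:
  study_years: [2001, 2002, 2003, 2004, 2005, 2006]
  annual_noninjury_deaths:
    28-364d: 92
    1-4y: 43
    5-18y: 90
  rti_fraction: 0.28
  winter_multiplier: 1.74
  annual_trend: 0.977
  p_linked: 0.63
rti_window_days: 30
chronic_lookback_days: 365
ci_method: wald
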