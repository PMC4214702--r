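# Example run configuration for il35sim (units follow the parameter table:
# rates 1/day, densities g/cm^3, lengths cm, times day).
scenario: J558-IL-35
days: 56            # 8-week horizon
n_cells: 100        # radial resolution
output_every: 1     # output cadence, day
seed: 1
overrides:
  # tumor IL-35 production rate, 1/day (here: 2x the preset baseline)
  lambda_rho_c: 6.9e-10
protocol:
  mode: continuous  # none | continuous | intermittent
  A0: 1             # dose strength, drug-concentration units
  duration_months: 2
  month_days: 28    # 28-day months keep equal-dose schedules exact
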