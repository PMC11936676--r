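# Example run configuration: Rocky Mountain aspen stand, western Montana
# (47.522 N, -113.668 E, 1230 m a.s.l.), spring interaction season.
#
# The monthly normals are synthetic station-style values for the site,
# calibrated so that the current-scenario simulation yields a maximum
# 1.2 m air temperature of 20.9 degC and a maximum sun-exposed leaf
# temperature of 25.7 degC over the May-July mid-month days. Scenario
# deltas are uniform additive warming offsets for the 2021-2040 horizon
# (intermediate- and high-emissions pathways).
seed: 20
site:
  latitude: 47.522
  longitude: -113.668
  elevation: 1230
  reference_height: 1.2
  transmittance: 0.70
  normals:
    - {month: 5, t_min: 1.5, t_max: 16.2, wind_mean: 0.5, rh_mean: 62, cloud_fraction: 0.55}
    - {month: 6, t_min: 5.3, t_max: 20.955, wind_mean: 0.4, rh_mean: 60, cloud_fraction: 0.3}
    - {month: 7, t_min: 7.8, t_max: 20.3, wind_mean: 0.5, rh_mean: 55, cloud_fraction: 0.35}
scenarios:
  - {name: current, delta: 0}
  - {name: intermediate, delta: 2.9}
  - {name: high, delta: 3.7}
leaf:
  absorptance: 0.5
  emissivity: 0.97
  dimension: 0.05
  stomatal_conductance: 0.2
designs:
  heat_shock_host:
    shock_temperatures: [38, 40, 42, 44, 46, 48.4]
    n_per_temperature: 60
    true_lt50: 42.1
    true_slope: -0.86
  heat_shock_parasitoid:
    shock_temperatures: [34, 36, 38, 40, 42, 44]
    n_per_temperature: 60
    true_lt50: 37.4
    true_slope: -0.25
  gradient:
    n_individuals: 135
    tpref_mean: 20.1
    tpref_sd: 4.5
    rearing_temperatures: [15, 20, 25, 30, 35]
    bar_cold_end: 12.5
    bar_hot_end: 44.5
    n_positions: 6
  emergence:
    rearing_temperatures: [15, 20, 25, 30, 35]
    n_leaves_per_temperature: 150
    host: {dd: 250, t0: 4, noise_sd: 3}
    parasitoid: {dd: 165, t0: 9.5, noise_sd: 3}
    emergence_probability: {host: 0.14, parasitoid: 0.36}
analysis:
  levene_center: median
  link: logit
months: [5, 6, 7]
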