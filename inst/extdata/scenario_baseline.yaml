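# Baseline forward-looking scenario: 10-yr NPV per mature-weight class
mature_weights: [430.84, 453.51, 476.19, 498.87, 521.54, 544.22, 566.89, 589.57, 612.24, 634.92]
grazing_days_grid: [175, 180, 185, 190, 195, 200, 205, 210, 215, 220, 225]
baseline_grazing_days: 200
horizon: 10
discount_rate: 0.05
total_land: 40.5
entry_age: 2
start_year: 2019
birth_wt: 35
peak_milk: 8
forage:
  nem_pasture: 1.43
  nem_hay: 1.20
  productivity: 5662
  utilization: 0.5
season:
  hay_days_cold: 115
  cold_stress_factor: 1.05
  hay_days_dry_base: 49
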