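year,marketing_rate,feed_land_ha,hay_ton,mineral_cow,vet_cow,equip_repair_ha,labor_cow,labor_wage_hr,other_var_ha,interest_rate,tax_rate,pasture_care_cow,pasture_care_ha,machinery_livestock_cow,misc_rate
2019,0.05,69.13,192.51,36.00,25.38,7.77,,14.61,16.48,0.05,0.028,,24.49,,0.10
2020,0.05,69.13,194.29,36.36,25.63,7.84,,15.05,16.65,0.05,0.028,,24.49,,0.10
2021,0.05,69.13,240.63,36.72,25.89,7.92,,15.49,16.81,0.05,0.028,,24.49,,0.10
2022,0.05,69.13,319.06,37.09,26.15,8.00,,15.93,16.98,0.05,0.028,,24.49,,0.10
2023,0.05,69.13,194.29,37.46,26.41,8.08,,16.37,17.15,0.05,0.028,,24.49,,0.10
2024,0.05,69.13,210.33,37.84,26.67,8.16,,16.81,17.32,0.05,0.028,,24.49,,0.10
2025,0.05,69.13,349.37,38.21,26.94,8.24,,17.25,17.50,0.05,0.028,,24.49,,0.10
2026,0.05,69.13,361.84,38.60,27.21,8.33,,17.69,17.67,0.05,0.028,,24.49,,0.10
2027,0.05,69.13,354.71,38.98,27.48,8.41,,18.16,17.85,0.05,0.028,,24.49,,0.10
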