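year,marketing_rate,feed_land_ha,hay_ton,mineral_cow,vet_cow,equip_repair_ha,labor_cow,labor_wage_hr,other_var_ha,interest_rate,tax_rate,pasture_care_cow,pasture_care_ha,machinery_livestock_cow,misc_rate
2011,0.05,31.72,196.00,32.72,22.73,7.22,30.75,,14.96,0.05,0.033,26.04,,28.06,0.10
2012,0.05,61.72,203.00,34.16,23.72,7.53,31.91,,15.62,0.05,0.033,26.04,,28.06,0.10
2013,0.05,64.19,199.00,34.79,24.16,7.67,32.97,,15.90,0.05,0.033,26.04,,28.06,0.10
2014,0.05,74.07,207.00,36.65,25.45,8.20,33.53,,17.00,0.05,0.033,26.04,,28.06,0.10
2015,0.05,74.07,161.00,36.23,25.16,7.99,34.83,,16.56,0.05,0.033,26.04,,28.06,0.10
2016,0.05,74.07,137.00,34.65,24.07,7.64,36.06,,15.84,0.05,0.033,26.04,,28.06,0.10
2017,0.05,69.14,147.00,34.88,24.22,7.69,37.00,,15.95,0.05,0.033,26.04,,28.06,0.10
2018,0.05,74.07,177.00,36.00,25.00,7.87,39.36,,16.32,0.05,0.033,26.04,,28.06,0.10
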