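column,table_row_label,unit
marketing_rate,"Marketing, 5% of revenue",fraction of revenue
feed_land_ha,"Feed, $/ha",$/ha
hay_ton,"Hay, $/ton",$/US short ton
mineral_cow,"Mineral, $/cow",$/cow
vet_cow,"Veterinary, medicine, and identification, $/cow",$/cow
equip_repair_ha,"Equipment, and facility repairs, $/ha",$/ha
labor_cow,"Labor, $/cow",$/cow
labor_wage_hr,"Labor, Wage, $/hour",$/hour
other_var_ha,"Other variable costs (fuel etc.), $/ha",$/ha
interest_rate,"Interest on operating capital",fraction of variable costs
tax_rate,"Taxes",fraction of expenditures
pasture_care_cow,"Pasture care, $/cow",$/cow
pasture_care_ha,"Pasture care, $/ha",$/ha
machinery_livestock_cow,"Machinery, Livestock, Interest, $/cow",$/cow
misc_rate,"Miscellaneous, 10% of overhead",fraction of overhead
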