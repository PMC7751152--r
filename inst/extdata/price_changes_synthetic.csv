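year,steer_price,heifer_price,cull_cow_price,cull_bull_price
2020,0.040,0.040,0.030,0.030
2021,0.020,0.020,0.020,0.020
2022,-0.030,-0.030,-0.020,-0.020
2023,0.100,0.100,0.080,0.080
2024,0.180,0.180,0.150,0.150
2025,0.120,0.120,0.100,0.100
2026,-0.150,-0.150,-0.120,-0.120
2027,-0.120,-0.120,-0.100,-0.100
2028,0.020,0.020,0.020,0.020
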