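year,steer_price,heifer_price,cull_cow_price,cull_bull_price
2011,2.87,2.64,1.28,1.42
2012,3.10,2.85,1.35,1.50
2013,3.20,2.94,1.38,1.53
2014,4.85,4.46,1.95,2.10
2015,4.40,4.05,1.70,1.88
2016,3.10,2.85,1.25,1.40
2017,3.25,2.99,1.30,1.45
2018,3.20,2.94,1.22,1.36
2019,3.15,2.90,1.20,1.34
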