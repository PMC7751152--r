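term,estimate,ci_lower,ci_upper
intercept,155.72,-38.82,350.26
ln_dbw,17.46,-12.99,47.91
birth_wt,0.37,-0.08,0.81
heifer,-5.23,-77.37,66.91
steer,45.00,-27.12,117.12
age,9.19,3.55,14.82
age2,-0.65,-1.09,0.02
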