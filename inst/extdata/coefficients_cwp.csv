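term,estimate,ci_lower,ci_upper
intercept,277.52,253.78,301.26
ln_dbw,-38.58,-42.25,-34.91
birth_wt,0.07,0.02,0.13
heifer,2.93,-6.38,12.25
steer,5.95,-3.36,15.27
age,0.98,0.29,1.67
age2,-0.06,-0.12,-0.01
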