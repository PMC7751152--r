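term,estimate,ci_lower,ci_upper
intercept,-47.07,-171.74,77.61
ln_dbw,36.92,17.61,56.22
birth_wt,0.37,0.10,0.65
heifer,17.73,-30.96,66.42
steer,33.79,-14.89,82.47
age,5.80,2.19,9.41
age2,-0.41,-0.69,-0.13
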