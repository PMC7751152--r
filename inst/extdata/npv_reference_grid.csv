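cow_kg,175,180,185,190,195,baseline,205,210,215,220,225
430.84,-585.56,-561.44,-537.32,-513.20,-489.08,-537.44,-443.04,-421.11,-399.18,-377.26,-355.33
453.51,-618.96,-594.85,-570.75,-546.64,-522.54,-496.63,-476.45,-454.46,-432.47,-410.48,-388.49
476.19,-654.92,-630.83,-606.74,-582.65,-558.56,-534.46,-512.42,-490.37,-468.33,-446.28,-424.23
498.87,-670.98,-646.90,-622.82,-598.74,-574.67,-550.59,-528.49,-506.39,-484.29,-462.19,-440.09
521.54,-687.17,-663.10,-639.03,-614.97,-590.90,-566.84,-544.69,-522.54,-500.39,-478.25,-456.10
544.22,-722.34,-698.29,-674.23,-650.18,-626.12,-602.07,-579.87,-557.68,-535.49,-513.29,-491.10
566.89,-739.43,-715.39,-691.34,-667.30,-643.25,-619.21,-596.97,-574.73,-552.50,-530.26,-508.03
589.57,-756.81,-732.78,-708.74,-684.71,-660.67,-636.64,-614.36,-592.08,-569.81,-547.53,-525.26
612.24,-774.59,-750.56,-726.53,-702.51,-678.48,-654.45,-632.14,-609.83,-587.51,-565.20,-542.89
634.92,-792.81,-768.80,-744.78,-720.76,-696.74,-672.72,-650.37,-628.03,-605.68,-583.33,-560.98
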