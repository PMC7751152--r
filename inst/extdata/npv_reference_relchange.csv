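cow_kg,175,180,185,190,195,baseline,205,210,215,220,225
430.84,-8.95,-4.47,0.02,4.51,9.00,0.00,17.56,21.64,25.72,29.80,33.88
453.51,-15.17,-10.68,-6.20,-1.71,2.77,7.59,11.35,15.44,19.53,23.62,27.71
476.19,-21.86,-17.38,-12.89,-8.41,-3.93,0.55,4.66,8.76,12.86,16.96,21.06
498.87,-24.85,-20.37,-15.89,-11.41,-6.93,-2.45,1.66,5.78,9.89,14.00,18.11
521.54,-27.86,-23.38,-18.90,-14.43,-9.95,-5.47,-1.35,2.77,6.89,11.01,15.13
544.22,-34.41,-29.93,-25.45,-20.98,-16.50,-12.03,-7.90,-3.77,0.36,4.49,8.62
566.89,-37.58,-33.11,-28.64,-24.16,-19.69,-15.21,-11.08,-6.94,-2.80,1.33,5.47
589.57,-40.82,-36.35,-31.87,-27.40,-22.93,-18.46,-14.31,-10.17,-6.02,-1.88,2.27
612.24,-44.13,-39.66,-35.18,-30.71,-26.24,-21.77,-17.62,-13.47,-9.32,-5.17,-1.01
634.92,-47.52,-43.05,-38.58,-34.11,-29.64,-25.17,-21.01,-16.86,-12.70,-8.54,-4.38
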