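prices_synthetic.csv and price_changes_synthetic.csv are SYNTHETIC stand-ins
for market price series (feeder steer/heifer prices, cull cow/bull prices,
$/kg live weight) that are not shipped with the package. The levels and the
cattle-cycle shape of the year-over-year changes are plausible for the upper
Midwest over 2011-2028 but are not observed market data; absolute dollar
outputs computed from them (budgets, NPV grids) characterize the method, not
the market. Users should substitute their own series in the same CSV layout.
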