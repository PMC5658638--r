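# Expert-panel weighting of the six consumer effort factors (% of total effort)
calls_pct: 40
denials_pct: 25
web_mobile_pct: 15
out_of_network_pct: 8
adjustments_pct: 7
household_pct: 5
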