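"key","value"
"horizon_cycles",20
"cycle_length_months",3
"annual_discount_rate",0.05
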