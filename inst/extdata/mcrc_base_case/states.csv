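"name","absorbing","order_index","initial_occupancy"
"first_line",FALSE,1,1
"second_line",FALSE,2,0
"supportive_care",FALSE,3,0
"death",TRUE,4,0
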