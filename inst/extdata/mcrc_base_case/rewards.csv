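"strategy","state","reward"
"XELOX","first_line",17.6
"XELOX","second_line",20.6
"XELOX","supportive_care",18
"XELOX+bevacizumab","first_line",19.8
"XELOX+bevacizumab","second_line",20.6
"XELOX+bevacizumab","supportive_care",18
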