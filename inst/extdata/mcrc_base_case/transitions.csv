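"strategy","from","to","probability"
"XELOX","first_line","first_line",0.66
"XELOX","first_line","second_line",0.2
"XELOX","second_line","second_line",0.49
"XELOX","first_line","supportive_care",0.08
"XELOX","second_line","supportive_care",0.45
"XELOX","supportive_care","supportive_care",0.75
"XELOX","first_line","death",0.06
"XELOX","second_line","death",0.06
"XELOX","supportive_care","death",0.25
"XELOX","death","death",1
"XELOX+bevacizumab","first_line","first_line",0.67
"XELOX+bevacizumab","first_line","second_line",0.12
"XELOX+bevacizumab","second_line","second_line",0.49
"XELOX+bevacizumab","first_line","supportive_care",0.16
"XELOX+bevacizumab","second_line","supportive_care",0.45
"XELOX+bevacizumab","supportive_care","supportive_care",0.75
"XELOX+bevacizumab","first_line","death",0.05
"XELOX+bevacizumab","second_line","death",0.06
"XELOX+bevacizumab","supportive_care","death",0.25
"XELOX+bevacizumab","death","death",1
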