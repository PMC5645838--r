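"strategy","state","category","amount"
"XELOX","first_line","medications",6428
"XELOX","first_line","preparation_pharmacy",81.24
"XELOX","first_line","administration_nursing",580.8
"XELOX","first_line","laboratory_tests",265.48
"XELOX","first_line","imaging_tests",900.8
"XELOX","second_line","medications",4327.8
"XELOX","second_line","preparation_pharmacy",270.18
"XELOX","second_line","administration_nursing",6700.74
"XELOX","second_line","laboratory_tests",409.08
"XELOX","second_line","imaging_tests",1276.2
"XELOX","supportive_care","laboratory_tests",265.48
"XELOX","supportive_care","hospitalization",4767.03
"XELOX+bevacizumab","first_line","medications",27592
"XELOX+bevacizumab","first_line","preparation_pharmacy",120.08
"XELOX+bevacizumab","first_line","administration_nursing",1006.4
"XELOX+bevacizumab","first_line","laboratory_tests",367
"XELOX+bevacizumab","first_line","imaging_tests",1720
"XELOX+bevacizumab","second_line","medications",4327.8
"XELOX+bevacizumab","second_line","preparation_pharmacy",270.18
"XELOX+bevacizumab","second_line","administration_nursing",6700.74
"XELOX+bevacizumab","second_line","laboratory_tests",409.08
"XELOX+bevacizumab","second_line","imaging_tests",1276.2
"XELOX+bevacizumab","supportive_care","laboratory_tests",265.48
"XELOX+bevacizumab","supportive_care","hospitalization",4767.03
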