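"parameter_id","kind","strategy","state","to_state","base","low","high","source"
"effectiveness.XELOX.first_line","effectiveness","XELOX","first_line",NA,17.6,15.8,19.3,"systematic review"
"effectiveness.XELOX.second_line","effectiveness","XELOX","second_line",NA,20.6,18.5,22.6,"FOLFIRI trial"
"effectiveness.XELOX.supportive_care","effectiveness","XELOX","supportive_care",NA,18,16.2,19.8,"supportive-care trial"
"effectiveness.XELOX+bevacizumab.first_line","effectiveness","XELOX+bevacizumab","first_line",NA,19.8,17.8,21.8,"systematic review"
"effectiveness.XELOX+bevacizumab.second_line","effectiveness","XELOX+bevacizumab","second_line",NA,20.6,18.5,22.6,"FOLFIRI trial"
"effectiveness.XELOX+bevacizumab.supportive_care","effectiveness","XELOX+bevacizumab","supportive_care",NA,18,16.2,19.8,"supportive-care trial"
"cost.XELOX.first_line","cost","XELOX","first_line",NA,8256.32,6636.06,9876.58,"micro-costing"
"cost.XELOX.second_line","cost","XELOX","second_line",NA,12984,11600.7,14367.3,"micro-costing"
"cost.XELOX.supportive_care","cost","XELOX","supportive_care",NA,5032.51,4529.26,5535.76,"micro-costing"
"cost.XELOX+bevacizumab.first_line","cost","XELOX+bevacizumab","first_line",NA,30805.48,20664,40946.96,"micro-costing"
"cost.XELOX+bevacizumab.second_line","cost","XELOX+bevacizumab","second_line",NA,12984,11600.7,14367.3,"micro-costing"
"cost.XELOX+bevacizumab.supportive_care","cost","XELOX+bevacizumab","supportive_care",NA,5032.51,4529.26,5535.76,"micro-costing"
"probability.XELOX.first_line.first_line","probability","XELOX","first_line","first_line",0.66,0.6,0.72,"assumed 10%"
"probability.XELOX.first_line.second_line","probability","XELOX","first_line","second_line",0.2,0.18,0.22,"pooled trials"
"probability.XELOX.first_line.supportive_care","probability","XELOX","first_line","supportive_care",0.08,0.07,0.09,"first-line trial"
"probability.XELOX.first_line.death","probability","XELOX","first_line","death",0.06,0.04,0.08,"pooled trials"
"probability.XELOX.second_line.second_line","probability","XELOX","second_line","second_line",0.49,0.45,0.53,"FOLFIRI trial"
"probability.XELOX.second_line.supportive_care","probability","XELOX","second_line","supportive_care",0.45,0.41,0.49,"FOLFIRI trial"
"probability.XELOX.second_line.death","probability","XELOX","second_line","death",0.06,0.04,0.08,"FOLFIRI trial"
"probability.XELOX.supportive_care.supportive_care","probability","XELOX","supportive_care","supportive_care",0.75,0.68,0.82,"supportive-care trial"
"probability.XELOX.supportive_care.death","probability","XELOX","supportive_care","death",0.25,0.23,0.27,"supportive-care trial"
"probability.XELOX+bevacizumab.first_line.first_line","probability","XELOX+bevacizumab","first_line","first_line",0.67,0.61,0.73,"assumed 10%"
"probability.XELOX+bevacizumab.first_line.second_line","probability","XELOX+bevacizumab","first_line","second_line",0.12,0.1,0.14,"pooled trials"
"probability.XELOX+bevacizumab.first_line.supportive_care","probability","XELOX+bevacizumab","first_line","supportive_care",0.16,0.14,0.18,"first-line trial"
"probability.XELOX+bevacizumab.first_line.death","probability","XELOX+bevacizumab","first_line","death",0.05,0.04,0.06,"pooled trials"
"probability.XELOX+bevacizumab.second_line.second_line","probability","XELOX+bevacizumab","second_line","second_line",0.49,0.45,0.53,"FOLFIRI trial"
"probability.XELOX+bevacizumab.second_line.supportive_care","probability","XELOX+bevacizumab","second_line","supportive_care",0.45,0.41,0.49,"FOLFIRI trial"
"probability.XELOX+bevacizumab.second_line.death","probability","XELOX+bevacizumab","second_line","death",0.06,0.04,0.08,"FOLFIRI trial"
"probability.XELOX+bevacizumab.supportive_care.supportive_care","probability","XELOX+bevacizumab","supportive_care","supportive_care",0.75,0.68,0.82,"supportive-care trial"
"probability.XELOX+bevacizumab.supportive_care.death","probability","XELOX+bevacizumab","supportive_care","death",0.25,0.23,0.27,"supportive-care trial"
"discount","discount",NA,NA,NA,0.05,0,0.1,"national HTA guideline"
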