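expert_id,scenario,target,term,polarity
e1,basic,awareness,high,1
e2,basic,awareness,very-high,1
e3,basic,awareness,high,1
e1,basic,attitude,low,1
e2,basic,attitude,medium,1
e3,basic,attitude,medium,1
e1,basic,attitude_price,medium,-1
e2,basic,attitude_price,low,-1
e3,basic,attitude_price,medium,-1
e1,basic,self_efficacy_1,medium,1
e2,basic,self_efficacy_1,medium,1
e3,basic,self_efficacy_1,medium,1
e1,basic,self_efficacy_2,very-low,1
e2,basic,self_efficacy_2,non-existent,1
e3,basic,self_efficacy_2,very-low,1
e1,plus,awareness,high,1
e2,plus,awareness,very-high,1
e3,plus,awareness,high,1
e1,plus,attitude,low,1
e2,plus,attitude,medium,1
e3,plus,attitude,medium,1
e1,plus,attitude_price,high,-1
e2,plus,attitude_price,medium,-1
e3,plus,attitude_price,high,-1
e1,plus,self_efficacy_1,high,1
e2,plus,self_efficacy_1,medium,1
e3,plus,self_efficacy_1,high,1
e1,plus,self_efficacy_2,very-low,1
e2,plus,self_efficacy_2,non-existent,1
e3,plus,self_efficacy_2,non-existent,1
e1,plus,availability_home,medium,1
e2,plus,availability_home,low,1
e3,plus,availability_home,medium,1
e1,plus,visibility_home,medium,1
e2,plus,visibility_home,medium,1
e3,plus,visibility_home,medium,1
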