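days,event,smoker,age_std,cg0001,cg0002,cg0003
120,1,1,0.5,0.82,0.11,0.40
340,0,0,-1.2,0.35,0.09,0.52
41,1,1,0.8,0.90,0.15,0.38
500,1,1,0.1,0.76,0.12,0.47
77,0,0,-0.3,0.41,0.08,0.55
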