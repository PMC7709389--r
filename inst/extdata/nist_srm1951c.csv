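level,analyte,elp,elp_sd,ref,ref_ci
1,TC,157.3,2.9,152.4,1.8
1,TG,153.0,1.7,152.0,3.2
1,HDLC,43.3,1.2,41.0,0.9
1,LDLC,87.0,1.7,86.4,1.4
2,TC,243.0,2.6,241.4,2.8
2,TG,139.7,1.5,145.4,3.2
2,HDLC,66.3,1.2,64.9,1.7
2,LDLC,152.0,1.0,143.8,2.1
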