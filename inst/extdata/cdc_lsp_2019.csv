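quarter_pool,analyte,measured,target
Q1/162,TC,166.9,169.4
Q1/163,TC,117.5,116.1
Q1/171,TC,176.4,176.2
Q2/171,TC,173.4,176.2
Q2/172,TC,157.8,160.7
Q2/485,TC,131.0,131.4
Q3/171,TC,178.8,176.2
Q3/172,TC,162.6,160.7
Q3/173,TC,184.0,187.9
Q4/174,TC,152.8,152.6
Q4/175,TC,187.9,189.4
Q4/A100,TC,182.4,183.5
Q1/162,TG,88.3,88.5
Q1/163,TG,74.5,73.0
Q1/171,TG,104.3,103.2
Q2/171,TG,102.9,103.2
Q2/172,TG,79.8,78.8
Q2/485,TG,107.9,106.8
Q3/171,TG,105.5,103.2
Q3/172,TG,82.4,78.8
Q3/173,TG,254.0,251.9
Q4/174,TG,85.4,88.0
Q4/175,TG,164.5,165.0
Q4/A100,TG,103.3,105.1
Q1/162,HDLC,58.3,55.3
Q1/163,HDLC,42.1,40.8
Q1/171,HDLC,56.9,55.7
Q2/171,HDLC,56.6,55.7
Q2/172,HDLC,51.6,51.8
Q2/485,HDLC,37.3,34.8
Q3/171,HDLC,57.9,55.7
Q3/172,HDLC,53.0,51.8
Q3/173,HDLC,36.5,37.3
Q4/174,HDLC,52.6,52.4
Q4/175,HDLC,54.4,54.4
Q4/A100,HDLC,57.3,55.5
Q1/162,APOB,83.9,83.7
Q1/163,APOB,58.4,53.8
Q1/171,APOB,84.1,86.3
Q2/171,APOB,83.4,86.3
Q2/172,APOB,82.9,80.3
Q2/485,APOB,72.4,70.3
Q3/171,APOB,87.0,86.3
Q3/172,APOB,84.8,80.8
Q3/173,APOB,106.9,104.8
Q4/174,APOB,75.9,70.8
Q4/175,APOB,97.1,93.7
Q4/A100,APOB,90.1,87.0
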