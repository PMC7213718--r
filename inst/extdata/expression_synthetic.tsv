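gene	P1	P2	P3
SCN5A	367.6	344.2	448.3
KCNH2	376.1	515.6	865.8
KCNJ2	128.7	305.5	172.3
KCNQ1	335.6	823.7	723.4
CACNA1C	263.9	170.7	514.3
KCNA4	217.3	303.7	457
ATP1A1	299.9	472.9	364.4
SLC8A1	71.2	163.7	130.9
ATP2B4	269.7	186.4	110.1
RYR2	287.9	713	618.7
ATP2A2	193.9	463	80.5
CALM1	293.3	168.1	245.2
CAMK2D	375.2	555.2	864.4
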