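pattern,n_aki,n_other
NONE,10949,391559
R,1850,37608
D,1297,19433
N,1872,50151
RD,1454,16600
RN,449,7438
DN,269,3783
RDN,275,2727
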