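# Pooled four-class epoch confusion matrix (reference rows x estimate
# columns) from a published clinical validation of chest-accelerometer
# sleep staging against polysomnography; used as the worked example for
# the row-percentage arithmetic. Stage codes: L = N1+N2, D = N3,
# R = REM, W = Wake.
ref,L,D,R,W
L,144578,10334,6558,10150
D,10943,21238,271,126
R,9744,45,36395,1001
W,14009,293,1865,50898
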