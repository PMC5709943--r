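replicate,sample_type,gene,role,plate,well,efficiency,cq
r1,A,g,target,plate1,A1,1.844,31.246
r1,A,g,target,plate1,A2,1.843,31.490
r1,A,g,target,plate1,A3,1.836,32.316
r1,B,g,target,plate1,B1,1.839,32.565
r1,B,g,target,plate1,B2,1.834,32.782
r1,B,g,target,plate1,B3,1.823,32.802
r1,A,ref1,reference,plate1,A4,1.905,26.645
r1,A,ref1,reference,plate1,A5,1.886,26.618
r1,A,ref1,reference,plate1,A6,1.868,26.579
r1,B,ref1,reference,plate1,B4,1.918,26.101
r1,B,ref1,reference,plate1,B5,1.906,26.096
r1,B,ref1,reference,plate1,B6,1.915,26.105
r1,A,ref2,reference,plate1,A7,1.900,26.191
r1,A,ref2,reference,plate1,A8,1.881,25.983
r1,A,ref2,reference,plate1,A9,1.879,25.962
r1,B,ref2,reference,plate1,B7,1.890,25.308
r1,B,ref2,reference,plate1,B8,1.883,25.256
r1,B,ref2,reference,plate1,B9,1.911,25.689
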