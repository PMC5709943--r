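replicate,sample_type,gene,role,plate,well,efficiency,cq
r1,A,g,target,plate1,A1,1.9,29.9142
r1,A,ref1,reference,plate1,A2,1.9,26.188
r1,A,ref2,reference,plate1,A3,1.9,25.4705
r1,B,g,target,plate1,B1,1.9,30.8792
r1,B,ref1,reference,plate1,B2,1.9,26.188
r1,B,ref2,reference,plate1,B3,1.9,25.4705
r2,A,g,target,plate2,A1,1.9,28.8606
r2,A,ref1,reference,plate2,A2,1.9,26.188
r2,A,ref2,reference,plate2,A3,1.9,25.4705
r2,B,g,target,plate2,B1,1.9,30.4606
r2,B,ref1,reference,plate2,B2,1.9,26.188
r2,B,ref2,reference,plate2,B3,1.9,25.4705
r3,A,g,target,plate3,A1,1.9,27.6194
r3,A,ref1,reference,plate3,A2,1.9,26.188
r3,A,ref2,reference,plate3,A3,1.9,25.4705
r3,B,g,target,plate3,B1,1.9,31.196
r3,B,ref1,reference,plate3,B2,1.9,26.188
r3,B,ref2,reference,plate3,B3,1.9,25.4705
r4,A,g,target,plate4,A1,1.9,28.3369
r4,A,ref1,reference,plate4,A2,1.9,26.188
r4,A,ref2,reference,plate4,A3,1.9,25.4705
r4,B,g,target,plate4,B1,1.9,30.0337
r4,B,ref1,reference,plate4,B2,1.9,26.188
r4,B,ref2,reference,plate4,B3,1.9,25.4705
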