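study,reference,topic,task,pathology,a1,mu2,lambda,r_squared,sse
a,Albert et al. 1979,famous faces,cued recall,korsakoff,0.000,0.018,0.941,0.978,0.0017
b,Albert et al. 1979,public events,cued recall,korsakoff,0.000,0.015,0.946,0.962,0.0025
c,Albert et al. 1979,public events,recognition 3AFC,korsakoff,0.148,0.000,0.778,0.967,0.0033
d,Albert et al. 1981,famous faces,cued recall,korsakoff,0.000,0.028,0.988,0.971,0.0035
e,Albert et al. 1981,public events,recognition 3AFC,korsakoff,0.000,0.008,0.777,0.173,0.1440
f,Kopelman 1989,news events,cued recall,korsakoff,0.077,0.011,0.957,0.857,0.0641
g,Parkin et al. 1990,famous faces,cued recall,korsakoff,0.108,0.001,0.779,0.956,0.0055
h,Parkin et al. 1990,famous faces,cued recall with context,korsakoff,0.078,0.004,0.779,0.609,0.0936
i,Squire et al. 1989,public events,cued recall,korsakoff,0.128,0.006,0.831,0.999,0.0003
j,Squire et al. 1989,public events,recognition 4AFC,korsakoff,0.096,0.006,0.670,0.793,0.0204
k,Beatty et al. 1988,mean of two tests,cued recall,korsakoff,0.059,0.001,0.959,0.887,0.0020
m,Beatty et al. 1988,mean of two tests,cued recall extra cues,korsakoff,0.068,0.001,0.960,0.979,0.0003
o,Kritchevsky & Squire 1989,public events,cued recall,tga,0.361,0.000,0.718,0.905,0.0140
p,Kritchevsky & Squire 1989,public events,recognition 4AFC,tga,0.663,0.000,0.369,0.955,0.0280
q,Reed & Squire 1998,mean of eight tests,mixed,partial_encephalitis,0.034,0.003,0.889,0.683,0.0049
r,Salmon et al. 1988,mean of two tests,cued recall,hypoxia,0.256,0.000,0.619,0.941,0.0277
s,Squire et al. 1989,public events,cued recall,focal,0.191,0.005,0.689,0.911,0.0376
t,Squire et al. 1989,public events,recognition 4AFC,focal,0.137,0.041,0.521,0.808,0.0338
u,Squire et al. 1990,TV series,recognition 4AFC,ect,4.751,0.000,1.000,0.749,0.1122
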