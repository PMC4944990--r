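dyad_id,sex,MD,TD,Pe,Ef,Fr,Na,HR_60,SDNN_60,rMSSD_60,HR_300,SDNN_300,rMSSD_300
1,MM,10,11,16,15,6,17,0.56,0.18,0.22,0.77,0.65,0.64
2,FF,10,12,10,14,11,13,0.19,0.38,-0.04,0.18,0.64,-0.02
3,MM,9,8,15,8,6,16,0.14,0.11,0.26,0.03,0.58,0.71
4,MF,11,11,12,15,14,17,0.63,0.38,0.18,0.80,0.56,0.23
5,MF,16,12,9,17,15,17,0.30,0.09,0.12,0.61,0.53,-0.22
6,MM,16,11,14,11,3,17,0.47,0.14,0.18,0.73,0.43,0.47
7,FF,13,11,9,15,17,16,-0.13,0.18,-0.05,-0.26,0.42,-0.24
8,MM,15,9,18,10,2,17,0.47,0.25,0.28,0.67,0.42,0.77
9,MF,10,10,9,10,7,15,0.32,0.04,0.14,0.37,0.41,0.06
10,FF,8,16,19,6,2,17,0.12,0.25,-0.18,-0.07,0.33,-0.54
11,MF,16,14,14,14,10,19,0.25,0.37,0.08,-0.09,0.33,0.18
12,MM,7,13,13,4,1,18,0.35,0.03,0.29,0.43,0.24,0.50
13,MF,14,11,10,16,11,12,0.01,0.28,0.17,-0.34,0.19,0.40
14,MF,12,11,15,17,10,20,0.11,0.22,0.15,0.02,0.15,0.50
15,MF,13,13,14,13,11,17,-0.20,0.09,-0.28,-0.42,0.15,-0.35
16,MM,13,14,18,11,4,19,-0.13,-0.01,-0.06,-0.60,0.00,-0.37
17,MF,11,11,9,10,9,10,0.37,0.16,0.31,0.67,-0.02,0.63
18,MF,13,14,12,15,8,17,0.34,0.13,-0.17,0.38,-0.11,-0.33
19,MF,12,16,6,18,14,15,0.31,-0.17,-0.16,0.35,-0.39,-0.27
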