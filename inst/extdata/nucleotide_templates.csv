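# Idealized deoxyribonucleotide geometries from the PDB Chemical Component Dictionary (ideal coordinates)
resid,name,element,x,y,z
DA,P,P,0.934,-0.156,-4.636
DA,OP1,O,1.781,0.996,-4.255
DA,OP2,O,-0.204,0.331,-5.665
DA,O5',O,0.241,-0.771,-3.320
DA,C5',C,-0.549,0.270,-2.744
DA,C4',C,-1.239,-0.251,-1.482
DA,O4',O,-0.267,-0.564,-0.458
DA,C3',C,-2.105,0.859,-0.835
DA,O3',O,-3.409,0.895,-1.418
DA,C2',C,-2.173,0.398,0.640
DA,C1',C,-0.965,-0.545,0.797
DA,N9,N,-0.078,-0.047,1.852
DA,C8,C,0.962,0.817,1.689
DA,N7,N,1.535,1.044,2.835
DA,C5,C,0.897,0.346,3.805
DA,C6,C,1.069,0.196,5.191
DA,N6,N,2.079,0.869,5.856
DA,N1,N,0.236,-0.603,5.850
DA,C2,C,-0.729,-1.249,5.224
DA,N3,N,-0.925,-1.144,3.927
DA,C4,C,-0.142,-0.368,3.184
DA,H5',H,-1.302,0.594,-3.463
DA,H5'',H,0.092,1.112,-2.486
DA,H4',H,-1.846,-1.126,-1.712
DA,H3',H,-1.617,1.830,-0.918
DA,H2',H,-3.103,-0.136,0.831
DA,H2'',H,-2.079,1.253,1.311
DA,H1',H,-1.309,-1.549,1.046
DA,H8,H,1.266,1.250,0.748
DA,H61,H,2.185,0.761,6.814
DA,H62,H,2.683,1.447,5.363
DA,H2,H,-1.383,-1.889,5.798
DC,P,P,0.987,-0.017,-3.894
DC,OP1,O,1.802,1.099,-3.365
DC,OP2,O,-0.119,0.560,-4.910
DC,O5',O,0.255,-0.772,-2.674
DC,C5',C,-0.571,0.196,-2.027
DC,C4',C,-1.300,-0.459,-0.852
DC,O4',O,-0.363,-0.863,0.171
DC,C3',C,-2.206,0.569,-0.129
DC,O3',O,-3.488,0.649,-0.756
DC,C2',C,-2.322,-0.040,1.288
DC,C1',C,-1.106,-0.981,1.395
DC,N1,N,-0.267,-0.584,2.528
DC,C2,C,0.270,0.648,2.563
DC,O2,O,0.052,1.424,1.647
DC,N3,N,1.037,1.035,3.581
DC,C4,C,1.291,0.212,4.589
DC,N4,N,2.085,0.622,5.635
DC,C5,C,0.746,-1.088,4.580
DC,C6,C,-0.035,-1.465,3.541
DC,H5',H,-1.302,0.583,-2.737
DC,H5'',H,0.046,1.015,-1.659
DC,H4',H,-1.885,-1.313,-1.193
DC,H3',H,-1.731,1.549,-0.094
DC,H2',H,-3.250,-0.602,1.387
DC,H2'',H,-2.266,0.742,2.046
DC,H1',H,-1.444,-2.009,1.526
DC,H41,H,2.461,1.516,5.636
DC,H42,H,2.265,0.019,6.373
DC,H5,H,0.943,-1.771,5.394
DC,H6,H,-0.467,-2.454,3.514
DG,P,P,-0.818,-0.321,4.935
DG,OP1,O,-1.774,0.766,4.630
DG,OP2,O,0.312,0.224,5.941
DG,O5',O,-0.126,-0.826,3.572
DG,C5',C,0.550,0.300,3.011
DG,C4',C,1.233,-0.113,1.706
DG,O4',O,0.253,-0.471,0.705
DG,C3',C,1.976,1.091,1.073
DG,O3',O,3.294,1.218,1.612
DG,C2',C,2.026,0.692,-0.421
DG,C1',C,0.897,-0.345,-0.573
DG,N9,N,-0.068,0.111,-1.575
DG,C8,C,-1.172,0.877,-1.341
DG,N7,N,-1.804,1.094,-2.458
DG,C5,C,-1.145,0.482,-3.472
DG,C6,C,-1.361,0.377,-4.866
DG,O6,O,-2.321,0.914,-5.391
DG,N1,N,-0.473,-0.327,-5.601
DG,C2,C,0.593,-0.928,-5.003
DG,N2,N,1.474,-1.643,-5.774
DG,N3,N,0.804,-0.839,-3.709
DG,C4,C,-0.027,-0.152,-2.917
DG,H5',H,1.299,0.661,3.715
DG,H5'',H,-0.170,1.093,2.808
DG,H4',H,1.921,-0.940,1.879
DG,H3',H,1.411,2.013,1.211
DG,H2',H,2.990,0.246,-0.665
DG,H2'',H,1.834,1.559,-1.053
DG,H1',H,1.316,-1.306,-0.873
DG,H8,H,-1.477,1.248,-0.373
DG,H1,H,-0.601,-0.413,-6.559
DG,H21,H,2.240,-2.073,-5.363
DG,H22,H,1.329,-1.722,-6.730
DT,P,P,-3.968,-1.665,3.118
DT,OP1,O,-4.406,-2.599,4.208
DT,OP2,O,-4.901,-0.360,2.920
DT,O5',O,-2.493,-1.028,3.315
DT,C5',C,-2.005,-0.136,2.327
DT,C4',C,-0.611,0.328,2.728
DT,O4',O,0.247,-0.829,2.764
DT,C3',C,0.008,1.286,1.720
DT,O3',O,0.965,2.121,2.368
DT,C2',C,0.710,0.360,0.754
DT,C1',C,1.157,-0.778,1.657
DT,N1,N,1.164,-2.047,0.989
DT,C2,C,2.333,-2.544,0.374
DT,O2,O,3.410,-1.945,0.363
DT,N3,N,2.194,-3.793,-0.240
DT,C4,C,1.047,-4.570,-0.300
DT,O4,O,0.995,-5.663,-0.857
DT,C5,C,-0.143,-3.980,0.369
DT,C7,C,-1.420,-4.757,0.347
DT,C6,C,-0.013,-2.784,0.958
DT,H5',H,-1.971,-0.654,1.366
DT,H5'',H,-2.683,0.718,2.254
DT,H4',H,-0.644,0.753,3.736
DT,H3',H,-0.722,1.941,1.236
DT,H2',H,-0.003,-0.001,0.003
DT,H2'',H,1.556,0.818,0.232
DT,H1',H,2.163,-0.604,2.054
DT,H3,H,3.023,-4.171,-0.689
DT,H71,H,-1.735,-4.916,-0.683
DT,H72,H,-2.195,-4.208,0.881
DT,H73,H,-1.272,-5.721,0.833
DT,H6,H,-0.857,-2.318,1.458
DU,P,P,-3.968,-1.665,3.118
DU,OP1,O,-4.406,-2.599,4.208
DU,OP2,O,-4.901,-0.360,2.920
DU,O5',O,-2.493,-1.028,3.315
DU,C5',C,-2.005,-0.136,2.327
DU,C4',C,-0.611,0.328,2.728
DU,O4',O,0.247,-0.829,2.764
DU,C3',C,0.008,1.286,1.720
DU,O3',O,0.965,2.121,2.368
DU,C2',C,0.710,0.360,0.754
DU,C1',C,1.157,-0.778,1.657
DU,N1,N,1.164,-2.047,0.989
DU,C2,C,2.334,-2.545,0.374
DU,O2,O,3.412,-1.946,0.363
DU,N3,N,2.195,-3.797,-0.241
DU,C4,C,1.046,-4.570,-0.300
DU,O4,O,0.971,-5.663,-0.852
DU,C5,C,-0.130,-3.976,0.367
DU,C6,C,-0.013,-2.784,0.958
DU,H5',H,-1.971,-0.654,1.366
DU,H5'',H,-2.683,0.718,2.254
DU,H4',H,-0.644,0.753,3.736
DU,H3',H,-0.722,1.941,1.236
DU,H2',H,-0.003,-0.001,0.003
DU,H2'',H,1.556,0.818,0.232
DU,H1',H,2.163,-0.604,2.054
DU,H3,H,3.023,-4.177,-0.691
DU,H5,H,-1.065,-4.523,0.362
DU,H6,H,-0.864,-2.330,1.454
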