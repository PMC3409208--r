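# peak list (sim-seed1002); m/z intensity; calibrated=FALSE
512.2827112	1050.023966
515.3300012	231.7481741
604.3664412	385.9553638
661.3667812	491.4701874
681.2694612	245.3803658
842.51	1102.439081
892.4192812	708.3576935
1004.440231	346.0744599
1042.276	1006.029607
1045.5642	1310.202858
1107.558151	739.5814345
1154.631651	948.9770611
1246.715381	634.7675967
1313.670881	1378.359402
1425.570791	750.2255955
1474.659071	1646.231911
1666.691851	980.1728095
1692.906751	1865.531969
1806.935751	1815.652488
1809.983041	276.0798408
2092.893851	2305.187587
2102.116088	464.5805735
2136.910691	1779.056672
2193.341743	2967.231248
2211.1046	285.7448288
2283.1807	3282.680199
2410.993181	169.9014217
2465.199	995.0972783
2514.111101	477.5004407
2832.792796	2722.809591
2966.295291	983.2953837
3548.535081	645.8441628
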