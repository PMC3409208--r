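# peak list (sim-seed1001); m/z intensity; calibrated=FALSE
403.2299512	4945.709304
512.2827112	1297.376816
515.3300012	891.2802581
604.3664412	179.664866
661.3667812	687.0518121
681.2694612	1539.29805
757.3739912	699.5469005
839.4232512	401.7700109
842.51	2867.535071
892.4192812	198.9318965
1004.440231	494.6921006
1008.445501	885.9717276
1042.276	1146.846139
1045.5642	950.5566854
1089.550971	1856.767328
1107.558151	1393.093087
1141.586101	589.755991
1154.631651	1140.637414
1246.715381	2032.053444
1313.670881	920.7288301
1425.570791	2118.840706
1474.659071	1693.053187
1666.691851	5967.161315
1692.906751	800.6134348
1712.824691	264.8360269
1746.801651	677.2369705
1758.783011	232.2498312
1806.935751	1375.125569
1809.983041	2747.726796
2092.893851	806.1837762
2119.081821	878.3845841
2136.910691	2951.372133
2142.995121	1619.384722
2211.1046	1639.342368
2283.1807	726.3625507
2332.95836	1818.141234
2408.977466	243.8010176
2410.993181	1068.877148
2465.199	7584.846811
2514.111101	2430.080322
2829.316141	1422.862404
2832.734812	373.8942631
2939.487231	981.9082327
2966.295291	10861.20531
3548.535081	925.7714856
6263.810131	1370.635682
7334.343261	487.4592678
8363.874111	658.5890517
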