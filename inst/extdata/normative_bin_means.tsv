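region	lobe	mean1	sd1	mean2	sd2	mean3	sd3	mean4	sd4	mean5	sd5	mean6	sd6	mean7	sd7
Thalamus	subcortical	16102.0	688.1	16068.8	767.5	15809.4	738.8	15120.0	859.2	14642.0	788.4	14097.8	723.3	13322.4	779.7
Caudate	subcortical	7211.5	456.6	7111.0	513.2	7018.5	423.7	6942.1	430.6	7024.6	509.3	7128.5	560.4	7707.0	693.6
Putamen	subcortical	10160.6	561.8	10029.8	602.7	9880.5	612.8	9615.7	623.0	9389.2	556.9	9210.0	674.4	9287.4	768.4
Pallidum	subcortical	4180.8	230.3	4167.0	232.5	4163.8	294.3	4000.1	288.8	3966.3	240.2	3983.8	331.4	4072.0	393.8
Hippocampus	subcortical	8768.0	398.0	8787.7	414.2	8844.8	479.3	8897.0	483.3	8759.4	473.0	8473.5	485.9	7831.8	835.4
Amygdala	subcortical	3504.3	195.0	3478.6	197.2	3485.8	186.6	3502.2	214.2	3414.9	225.4	3284.8	255.1	3143.3	295.2
Accumbens Area	subcortical	1117.3	90.9	1089.6	93.0	1033.8	89.7	1010.6	96.1	957.0	90.7	898.2	101.5	837.6	127.4
Ventral DC	subcortical	8386.9	386.2	8341.9	435.5	8346.0	491.1	8214.9	495.3	8076.4	440.8	7974.4	422.7	7849.0	477.4
Choroid Plexus	subcortical	1038.0	219.2	1083.0	231.3	1283.5	294.4	1469.5	335.8	1747.6	335.4	2115.8	373.0	2360.5	162.6
Caudal Middle Frontal	frontal	12486.5	1289.9	12190.6	1250.7	11793.3	1075.4	11625.6	1252.8	11601.5	1138.3	11139.7	1170.7	10887.9	935.7
Rostral Middle Frontal	frontal	21922.7	1836.4	21147.6	1830.5	20376.7	1771.8	19325.9	1677.7	18969.4	1484.8	18126.7	1475.3	17371.2	1432.5
Superior Frontal	frontal	49810.0	2707.4	48641.8	2775.8	46321.7	2214.7	45332.9	2560.8	44283.4	2330.1	43587.9	2406.9	41341.8	2261.1
Lateral Orbitofrontal	frontal	16931.2	847.9	16654.9	808.6	16418.7	869.3	15908.3	966.5	15625.4	834.8	15294.0	857.0	15007.5	916.1
Medial Orbitofrontal	frontal	8646.1	518.0	8520.1	482.5	8340.2	505.5	8048.9	487.6	7992.3	519.8	7988.3	534.5	7867.5	552.3
Pars Opercularis	frontal	8591.5	912.9	8391.1	834.6	7924.6	747.6	7772.4	820.8	7474.0	720.3	7508.6	787.8	7032.7	796.8
Pars Orbitalis	frontal	4177.4	410.2	4064.4	387.3	3928.5	409.6	3779.9	425.1	3751.0	368.7	3593.5	395.4	3499.9	333.1
Pars Triangularis	frontal	8471.4	975.3	8269.6	937.3	7691.0	814.3	7410.3	823.6	7289.9	791.9	7032.1	795.4	6829.2	958.6
Precentral	frontal	26147.5	1431.3	25919.3	1369.7	25607.4	1387.9	24979.6	1552.2	24818.3	1374.3	24348.9	1496.9	23461.5	1441.3
Inferior Parietal	parietal	27287.2	1952.5	26695.6	1992.0	26114.9	1944.4	25159.9	1825.0	24746.4	1842.8	23891.7	1691.4	23666.2	2030.8
Superior Parietal	parietal	21753.5	1611.4	21716.2	1719.9	21267.4	1564.3	20734.9	1808.0	20616.4	1590.7	20077.9	1558.4	19371.4	1470.0
Supramarginal	parietal	19751.3	1637.2	19461.2	1526.4	18719.0	1430.9	18264.1	1567.7	18066.0	1288.4	17607.1	1387.9	17657.9	1630.6
Paracentral	parietal	8340.5	623.4	8343.9	584.7	8147.6	554.2	8090.1	650.3	8025.3	568.7	7708.5	636.0	7646.3	573.3
Postcentral	parietal	20243.6	1400.3	20076.8	1296.3	19877.4	1318.6	19422.3	1384.0	19411.2	1211.2	19139.8	1454.1	17722.2	1240.4
Precuneus	parietal	20202.4	1240.8	19936.1	1234.8	19312.6	1273.6	18910.9	1298.3	18489.6	1219.5	17945.4	1173.6	17322.5	1186.0
Entorhinal	temporal	3411.4	322.7	3470.3	298.7	3632.6	340.9	3752.8	361.5	3679.4	339.2	3638.2	373.7	3505.2	387.2
Fusiform	temporal	16032.7	1086.1	15856.8	1125.0	15620.9	1261.7	15395.1	1214.5	14963.8	1086.5	14581.6	1347.1	13755.0	1240.8
Inferior Temporal	temporal	23026.8	1647.3	22664.4	1548.8	22535.3	1482.2	21944.0	1622.5	21812.1	1579.1	21174.2	1495.5	20603.2	1631.4
Middle Temporal	temporal	27488.6	1821.6	26742.5	1861.2	26247.9	1761.3	25274.7	1792.8	24914.6	1756.3	23925.7	1578.1	23286.0	2112.2
Superior Temporal	temporal	31945.2	1668.5	31279.1	1568.6	30832.1	1618.9	30421.5	1558.1	29670.2	1551.5	29069.7	1712.7	28501.4	1487.0
Transverse Temporal	temporal	2205.9	244.0	2193.3	232.9	2116.8	243.1	2058.1	232.7	2010.6	221.4	1994.5	253.8	1900.3	187.5
Parahippocampal	temporal	4195.2	324.6	4164.5	338.7	4145.6	349.0	4178.7	332.6	4075.0	342.4	3954.4	379.8	3780.6	247.1
Insula	temporal	11845.5	644.0	11737.2	582.7	11488.9	644.2	11347.3	629.4	11431.3	634.0	11373.1	755.1	11413.8	1118.6
Cuneus	occipital	7958.4	765.0	7940.5	741.5	7865.3	748.9	7749.6	803.3	7669.7	744.0	7540.5	663.6	7468.2	526.6
Lateral Occipital	occipital	22105.1	1766.5	22295.0	1706.9	21948.6	1654.1	21488.2	1513.2	21195.1	1676.5	20724.8	1676.3	20073.3	1273.8
Lingual	occipital	12681.7	1089.6	12880.7	1005.3	12539.5	1056.1	12370.2	1056.1	12233.9	1130.4	11887.0	1029.4	11389.9	512.2
Pericalcarine	occipital	4069.3	565.2	4056.7	493.3	4048.5	495.2	4013.9	566.5	3976.2	525.9	3939.4	525.0	3946.7	292.7
Caudal Anterior Cingulate	cingulate	5427.4	594.8	5325.9	581.9	5129.6	551.3	5028.3	598.6	4935.4	567.2	4780.5	530.3	4597.4	488.7
Isthmus Cingulate	cingulate	5049.1	417.7	4998.5	412.2	4861.3	417.9	4770.4	411.7	4770.6	411.2	4643.4	361.8	4380.2	303.4
Posterior Cingulate	cingulate	6687.3	511.6	6613.4	519.0	6401.5	495.1	6218.5	548.7	6162.3	515.5	5947.1	546.6	5720.0	505.6
Rostral Anterior Cingulate	cingulate	5908.0	630.6	5772.6	605.3	5596.6	651.2	5536.7	606.6	5386.2	536.7	5331.2	539.6	5102.2	562.1
3rd Ventricle	other	925.8	233.6	981.8	246.3	1108.1	286.4	1263.6	379.2	1517.8	512.5	1779.5	484.5	2145.6	408.1
4th Ventricle	other	1623.1	461.3	1620.7	471.1	1594.7	454.9	1719.7	512.6	1783.0	492.2	1804.8	498.5	1847.1	654.0
Brain Stem	other	20063.7	1481.9	20276.2	1682.3	20919.9	1648.7	21066.2	1758.4	20800.3	1784.5	20757.4	1625.8	21137.5	1663.5
CSF	other	1038.2	210.1	1060.7	186.9	1105.4	218.7	1122.5	254.0	1306.4	258.6	1432.0	310.3	1574.8	347.1
Cerebellum Cortex	other	104041.9	5217.2	103116.1	5434.5	102503.6	5056.1	101774.1	6110.6	100470.9	5205.3	99246.9	5330.8	99111.7	8363.4
Cerebellum White Matter	other	27770.2	1743.4	27792.8	1964.6	28310.0	2200.3	27778.5	2124.5	26715.3	1880.9	26458.7	2042.4	25720.5	2719.7
Cerebral White Matter	other	439677.3	32474.0	440415.1	33528.7	439806.4	35521.2	428620.7	36962.6	410573.7	34680.2	401222.6	31738.3	369167.5	27960.6
Inf Lat Vent	other	519.2	192.9	561.7	198.5	661.9	213.3	769.6	259.6	956.6	415.8	1288.8	477.1	1968.0	568.8
Lateral Ventricle	other	11665.7	4590.5	12965.3	4428.5	16186.8	5277.9	18347.8	6583.2	25387.0	8283.9	33083.3	10544.6	43811.9	11977.9
WM Hypointensities	other	1228.9	305.5	1282.3	296.6	1441.9	392.5	1715.7	744.2	2306.2	1525.2	3634.4	3037.0	5121.1	2555.4
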