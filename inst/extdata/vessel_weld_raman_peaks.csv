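weld_time_s,sample,band,position_cm1,intensity,fwhm_cm1
15,1,1247,1247.30,3227.29,37.00
15,1,1325,1322.71,1409.34,51.15
15,2,1247,1246.21,3220.33,41.38
15,2,1325,1315.23,1433.47,72.50
15,3,1247,1247.30,3038.43,41.37
15,3,1325,1312.01,1297.59,74.68
20,1,1247,1247.30,1087.83,52.28
20,1,1325,1317.37,630.84,95.95
20,2,1247,1250.56,1856.38,56.61
20,2,1325,1313.08,1158.75,129.73
20,3,1247,1249.47,1357.60,54.44
20,3,1325,1306.66,876.44,110.86
25,1,1247,1248.38,1704.50,43.54
25,1,1325,1319.51,888.80,76.68
25,2,1247,1245.13,2165.38,39.20
25,2,1325,1315.23,1223.91,87.36
25,3,1247,1246.21,2669.64,43.56
25,3,1325,1322.71,1511.89,78.74
25,4,1247,1249.47,1464.48,43.53
25,4,1325,1314.16,775.89,85.26
30,1,1247,1266.29,3484.08,75.66
30,1,1325,1303.85,5100.98,38.42
30,2,1247,1261.98,1086.55,71.38
30,2,1325,1304.92,1502.61,38.41
30,3,1247,1255.51,422.15,47.59
30,3,1325,1310.26,634.66,31.98
30,4,1247,1258.15,3203.23,97.10
30,4,1325,1307.73,3251.95,95.99
30,5,1247,1253.91,1869.72,60.94
30,5,1325,1304.51,1999.29,62.02
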