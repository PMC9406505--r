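fold,accuracy_pct,distance_mean_mm,distance_sd_mm,dist_le5_pct,dist_le10_pct,dist_le15_pct,dist_le20_pct,tip_recall_pct,tip_precision_pct,carina_recall_pct,carina_precision_pct,tip_mean_mm,tip_sd_mm,carina_mean_mm,carina_sd_mm
1,90.37,5.130,5.609,62.57,85.29,93.58,96.79,90.64,91.37,94.65,94.91,4.415,5.281,3.952,3.345
2,87.70,5.969,8.325,63.10,84.22,92.25,95.72,89.30,89.54,93.58,93.58,4.858,7.869,4.236,3.663
3,88.24,5.256,5.491,63.90,83.96,92.25,95.45,90.91,92.14,92.25,92.49,3.974,4.405,4.322,3.947
4,86.63,5.437,6.663,63.90,87.17,92.78,97.06,91.18,91.42,94.92,95.17,4.584,6.273,3.895,3.527
5,91.18,4.874,5.111,64.44,88.50,93.85,97.06,92.78,93.53,94.12,94.37,3.690,3.800,4.185,3.793
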