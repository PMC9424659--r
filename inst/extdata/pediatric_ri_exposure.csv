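infection,age_group,status,dose_mg_per_kg,interval_h,auc_0_24,cmax
CSSSI,12-17,HEALTHY,5,24,487.16,68.38
CSSSI,12-17,MILD,5,24,478.45,63.68
CSSSI,12-17,MODERATE,5,48,526.88,56.81
CSSSI,12-17,SEVERE,5,48,603.72,48.83
CSSSI,12-17,ESRD,5,48,650.29,42.24
CSSSI,7-11,HEALTHY,7,24,490.41,90.49
CSSSI,7-11,MILD,7,24,492.74,84.07
CSSSI,7-11,MODERATE,7,24,583.18,75.63
CSSSI,7-11,SEVERE,7,48,729.77,66.76
CSSSI,7-11,ESRD,7,48,848.82,58.99
CSSSI,2-6,HEALTHY,9,24,438.36,90.01
CSSSI,2-6,MILD,9,24,446.94,82.81
CSSSI,2-6,MODERATE,9,24,560.18,75.36
CSSSI,2-6,SEVERE,9,48,762.94,70.08
CSSSI,2-6,ESRD,9,48,963.57,64.72
CSSSI,1-2,HEALTHY,10,24,528.11,97.47
CSSSI,1-2,MILD,10,24,550.29,89.21
CSSSI,1-2,MODERATE,10,24,679.98,80.6
CSSSI,1-2,SEVERE,10,48,906.76,75.99
CSSSI,1-2,ESRD,10,48,1125.8,71.36
BACTEREMIA,12-17,HEALTHY,7,24,683.13,95.89
BACTEREMIA,12-17,MILD,7,24,670.91,89.3
BACTEREMIA,12-17,MODERATE,7,24,738.83,79.67
BACTEREMIA,12-17,SEVERE,7,48,846.58,68.47
BACTEREMIA,12-17,ESRD,7,48,911.89,59.22
BACTEREMIA,7-11,HEALTHY,9,24,629.77,116.2
BACTEREMIA,7-11,MILD,9,24,632.77,107.95
BACTEREMIA,7-11,MODERATE,9,24,748.9,97.12
BACTEREMIA,7-11,SEVERE,9,48,937.15,85.73
BACTEREMIA,7-11,ESRD,9,48,1090,75.75
BACTEREMIA,1-6,HEALTHY,12,24,584.48,120.01
BACTEREMIA,1-6,MILD,12,24,595.92,110.41
BACTEREMIA,1-6,MODERATE,12,24,746.9,100.48
BACTEREMIA,1-6,SEVERE,12,48,1017.3,93.44
BACTEREMIA,1-6,ESRD,12,48,1284.8,86.29
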