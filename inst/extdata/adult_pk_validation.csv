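label,metric,observed,predicted,source
healthy adult 6 mg/kg q24h,AUC,708.86,580,Benvenuto 2006
healthy adult 6 mg/kg q24h,CMAX,97.605,86.347,Benvenuto 2006
healthy adult 8 mg/kg q24h,AUC,742.63,772.99,Benvenuto 2006
healthy adult 8 mg/kg q24h,CMAX,108.85,115.13,Benvenuto 2006
healthy adult 10 mg/kg q24h,AUC,912.73,966.24,Benvenuto 2006
healthy adult 10 mg/kg q24h,CMAX,130.55,143.91,Benvenuto 2006
healthy adult 12 mg/kg q24h,AUC,1180,1159.5,Benvenuto 2006
healthy adult 12 mg/kg q24h,CMAX,168.39,172.69,Benvenuto 2006
healthy adult 4 mg/kg q24h,AUC,361.04,386.49,Dvorchik 2003
healthy adult 4 mg/kg q24h,CMAX,54.595,57.563,Dvorchik 2003
healthy adult 6 mg/kg q24h,AUC,587.05,579.74,Dvorchik 2003
healthy adult 6 mg/kg q24h,CMAX,86.487,86.345,Dvorchik 2003
healthy adult 8 mg/kg q24h,AUC,897.06,772.99,Dvorchik 2003
healthy adult 8 mg/kg q24h,CMAX,116.22,115.13,Dvorchik 2003
RI cohort healthy 10 mg/kg q24h,AUC,854.92,961.05,Gregoire 2019
RI cohort healthy 10 mg/kg q24h,CMAX,134.57,139.04,Gregoire 2019
RI cohort mild 10 mg/kg q24h,AUC,940,1023.1,Gregoire 2019
RI cohort mild 10 mg/kg q24h,CMAX,138.25,137.5,Gregoire 2019
RI cohort moderate 10 mg/kg q24h,AUC,896.85,1087,Gregoire 2019
RI cohort moderate 10 mg/kg q24h,CMAX,105.55,122.54,Gregoire 2019
RI cohort severe 10 mg/kg q48h,AUC,1403.9,1737.3,Gregoire 2019
RI cohort severe 10 mg/kg q48h,CMAX,114.45,104.64,Gregoire 2019
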