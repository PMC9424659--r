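label,metric,observed,predicted,source
child 12-17y 4 mg/kg q24h,AUC,374.4,386.42,Abdel-Rahman 2008
child 12-17y 4 mg/kg q24h,CMAX,50,54.24,Abdel-Rahman 2008
child 7-11y 4 mg/kg q24h,AUC,271,282.25,Abdel-Rahman 2008
child 7-11y 4 mg/kg q24h,CMAX,48,52.08,Abdel-Rahman 2008
child 2-6y 4 mg/kg q24h,AUC,215.3,194.92,Abdel-Rahman 2008
child 2-6y 4 mg/kg q24h,CMAX,43.8,47.15,Abdel-Rahman 2008
child 12-17y 5 mg/kg q24h,AUC,434,487.16,FDA label
child 12-17y 5 mg/kg q24h,CMAX,76.4,68.38,FDA label
child 7-11y 7 mg/kg q24h,AUC,543,490.41,FDA label
child 7-11y 7 mg/kg q24h,CMAX,92.4,90.49,FDA label
child 2-6y 9 mg/kg q24h,AUC,452,438.36,FDA label
child 2-6y 9 mg/kg q24h,CMAX,90.3,90.01,FDA label
child 1-2y 10 mg/kg q24h,AUC,462,528.11,FDA label
child 1-2y 10 mg/kg q24h,CMAX,81.6,97.47,FDA label
child 12-17y 7 mg/kg q24h,AUC,656,764.9,FDA label
child 12-17y 7 mg/kg q24h,CMAX,104,104.07,FDA label
child 7-11y 9 mg/kg q24h,AUC,579,657.3,FDA label
child 7-11y 9 mg/kg q24h,CMAX,104,119.37,FDA label
child 1-6y 12 mg/kg q24h,AUC,620,598.1,FDA label
child 1-6y 12 mg/kg q24h,CMAX,106,120.91,FDA label
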