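model,variant,metric,value,ci
dt,cross_subject,precision,60.57,0.66
dt,cross_subject,recall,61.32,0.53
dt,cross_subject,accuracy,60.08,0.49
dt,cross_subject,f1,60.94,0.59
dt,personalized,precision,61.77,0.58
dt,personalized,recall,65.83,0.49
dt,personalized,accuracy,65.97,0.67
dt,personalized,f1,63.75,0.53
ann,cross_subject,precision,73.29,0.43
ann,cross_subject,recall,78.53,0.39
ann,cross_subject,accuracy,82.41,0.58
ann,cross_subject,f1,75.82,0.41
ann,personalized,precision,80.25,0.47
ann,personalized,recall,83.08,0.43
ann,personalized,accuracy,85.79,0.48
ann,personalized,f1,81.64,0.45
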