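model,variant,pct_test_data,accuracy,ci
dt,cross_subject,0,60.08,0.49
dt,personalized,20,76.08,0.71
dt,subject_specific,100,88.75,0.59
ann,cross_subject,0,82.41,0.58
ann,personalized,20,92.74,0.49
ann,subject_specific,100,99.30,0.37
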