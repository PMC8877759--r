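model,family,fraction,n_reps,accuracy,delta_accuracy,agr
dt,subject_specific,0.0,0,15.34,,
dt,subject_specific,0.1,8,41.30,25.96,3.25
dt,subject_specific,0.2,15,58.40,17.10,1.14
dt,subject_specific,0.3,23,68.60,10.20,0.44
dt,subject_specific,0.4,30,78.90,10.30,0.34
dt,subject_specific,0.5,38,82.20,3.30,0.09
dt,subject_specific,0.6,45,84.03,1.83,0.04
dt,personalized,0.0,0,65.88,,
dt,personalized,0.1,8,70.64,4.76,0.60
dt,personalized,0.2,15,76.08,5.44,0.36
dt,personalized,0.3,23,77.77,1.69,0.07
dt,personalized,0.4,30,79.15,1.38,0.05
dt,personalized,0.5,38,79.55,0.40,0.01
dt,personalized,0.6,45,79.91,0.36,0.01
ann,subject_specific,0.0,0,55.23,,
ann,subject_specific,0.1,8,62.48,7.25,0.91
ann,subject_specific,0.2,15,74.68,12.20,0.81
ann,subject_specific,0.3,23,82.95,8.27,0.36
ann,subject_specific,0.4,30,87.37,4.42,0.15
ann,subject_specific,0.5,38,90.45,3.08,0.08
ann,subject_specific,0.6,45,92.99,2.54,0.06
ann,personalized,0.0,0,84.54,,
ann,personalized,0.1,8,87.37,2.83,0.35
ann,personalized,0.2,15,92.74,5.37,0.36
ann,personalized,0.3,23,93.56,0.82,0.04
ann,personalized,0.4,30,93.88,0.32,0.01
ann,personalized,0.5,38,94.25,0.37,0.01
ann,personalized,0.6,45,94.78,0.53,0.01
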