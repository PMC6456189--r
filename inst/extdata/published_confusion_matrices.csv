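analysis,positive_class,classifier,selection,tp,fn,fp,tn,printed_accuracy,printed_auc,printed_precision,printed_recall,printed_f_score
nsa_1,non_observable,svm,correlation,33,4,7,10,79.6,0.74,NA,NA,NA
nsa_2,non_observable,svm,correlation,26,7,9,12,70.4,0.68,NA,NA,NA
nsa_3,non_observable,svm,correlation,18,9,13,14,59.3,0.59,NA,NA,NA
nsa_5,non_observable,svm,correlation,13,12,13,16,53.7,0.54,NA,NA,NA
nsa_6,non_observable,svm,correlation,13,13,9,19,59.3,0.59,NA,NA,NA
nsa_8,non_observable,svm,correlation,6,7,7,34,74.1,0.65,NA,NA,NA
nsa_15,non_observable,svm,cfssubset,30,5,7,12,77.8,0.74,NA,NA,NA
patient_vs_healthy,patient,svm,relieff,40,14,10,16,70.0,0.68,0.80,0.74,0.77
patient_vs_healthy,patient,random_forest,cfssubset,42,12,10,16,72.5,0.80,0.81,0.78,0.79
patient_vs_healthy,patient,mlp,none,44,10,5,21,81.3,0.90,0.90,0.82,0.85
patient_vs_healthy,patient,bagging,cfssubset,46,8,10,16,77.5,0.80,0.82,0.85,0.84
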