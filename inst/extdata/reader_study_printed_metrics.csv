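set,images,n,accuracy,sensitivity,specificity,ppv,npv,auc,auc_lo,auc_hi
internal,input,47,0.64,0.81,0.55,0.48,0.85,0.68,0.53,0.81
internal,output,47,0.85,1.00,0.77,0.70,1.00,0.88,0.76,0.96
external,input,26,0.65,0.79,0.29,0.75,0.33,0.54,0.33,0.73
external,output,26,0.81,0.95,0.43,0.82,0.75,0.69,0.49,0.85
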