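class,lower_mb,mean_length_mb,mean_n_per_dog,coverage_pct,class_froh,class_froh_sd
1-2,1,1.41,34.87,2.23,0.31,0.06
2-4,2,2.84,23.40,3.02,0.29,0.06
4-8,4,5.68,20.47,5.27,0.26,0.06
8-16,8,11.26,16.08,8.22,0.21,0.06
>16,16,26.39,10.55,12.63,0.13,0.05
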