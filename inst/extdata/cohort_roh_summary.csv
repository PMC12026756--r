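cohort,snp_total_roh_kb,wgs_total_roh_kb,snp_mean_roh_kb,wgs_mean_roh_kb,snp_n_roh,wgs_n_roh
bearded_collie,691315,NA,6586,NA,105,NA
bearded_collie_subset,781741,710594,6854,293,114,2468
pedigree,543716,570736,5060,190,106,2989
mixed_breed,187952,150968,3654,141,43,924
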