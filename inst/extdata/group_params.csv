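group,n,hrw_mean,hrw_sd,mrw_mean,mrw_sd,lcci_mean,lcci_sd,hrw_temporal_frac,mrw_temporal_frac,disc_area_mean,disc_area_sd,ovality_mean,ovality_sd,age_mean,age_sd,iop_mean,iop_sd,se_mean,se_sd,male_frac,rnfl_global_mean,rnfl_global_sd,rnfl_ts_mean,rnfl_ts_sd,rnfl_t_mean,rnfl_t_sd,rnfl_ti_mean,rnfl_ti_sd,rnfl_ni_mean,rnfl_ni_sd,rnfl_n_mean,rnfl_n_sd,rnfl_ns_mean,rnfl_ns_sd
NTG,31,157.6,73.1,111.4,42.8,10.8,2.3,0.9334,0.8878,2.56,0.41,1.05,0.07,62.6,17.0,11.1,2.4,-0.67,2.25,0.452,46.0,10.4,51.5,23.2,40.9,12.6,44.5,14.3,50.8,12.9,44.2,11.4,51.1,17.8
CRAO,31,326.6,130.8,134.3,35.6,7.1,2.1,0.9134,0.9442,2.55,0.46,1.09,0.10,62.2,17.1,10.9,3.1,-0.05,1.43,0.452,41.7,9.8,48.5,14.3,37.7,11.0,48.4,20.0,42.9,13.4,37.7,9.7,42.9,14.7
healthy,31,362.2,85.8,217.9,29.9,7.1,1.4,0.9445,0.8789,2.50,0.45,1.05,0.08,62.2,17.1,10.1,1.9,-0.03,1.19,0.452,101.6,10.5,134.2,18.2,75.7,11.0,149.8,19.7,109.9,18.6,72.2,11.3,116.7,26.7
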