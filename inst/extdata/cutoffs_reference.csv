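bead_id,neg_mean,neg_sd,cutoff,n_controls
GPIa/IIa,NA,NA,132.29,NA
GPIba/IX,NA,NA,85.19,NA
HLA,NA,NA,131.97,NA
GPIIb/IIIa,NA,NA,163.46,NA
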