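patient_id,sex,rho,r_pre_um,r_post_um,ecf_pre,ecf_post,binding,qrs_model_pre_ms,qrs_model_post_ms
1,female,0.875890172443033,13.7074585871359,12.0062282656422,0,0.05,pre,76.7936280692517,72.8381849016057
2,male,0.970302164699528,12.4392494044655,12.0698306243901,0,0,post,83.162088249606,81.0459375443185
3,male,0.952607508500896,13.6022925036378,12.9576459717909,0.05,0,post,83.8030337875824,82.9051686668504
4,female,0.926203821690625,12.2086452660661,11.3076939030955,0,0,pre,75.6572317326859,74.7813626740856
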