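patient_id,sex,timepoint,qrs_ms,ecv,wt_mm,lv_volume_ml,bsa_m2
1,female,pre,76.7936280692517,0.220170074625887,10.422407155904,101.002109270037,1.74011515218279
1,female,post,72.8381849016057,0.261873283125687,8.44765781764525,81.8650859835534,1.74011515218279
2,male,pre,83.162088249606,0.272906467918588,11.8913548805507,114.893100558406,1.62266458677617
2,male,post,81.0459375443185,0.267480272528496,11.1126157321034,107.368999546361,1.62266458677617
3,male,pre,83.8030337875824,0.211719590906145,12.9275639240733,129.398167594152,2.07404846848196
3,male,post,82.9051686668504,0.244613211875807,12.242103396831,122.537065478996,2.07404846848196
4,female,pre,75.6572317326859,0.231136423591039,8.87118793325973,113.430796334763,1.88031784249921
4,female,post,74.7813626740856,0.239448271217715,7.69334922042592,98.3704476919675,1.88031784249921
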