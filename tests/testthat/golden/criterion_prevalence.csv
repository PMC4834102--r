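criterion_id,numerator,denominator,percent,ci_low,ci_high
opioid_no_laxative,19,195,9.7,5.6,13.9
ppi_high_dose_gt8w,16,195,8.2,4.4,12.1
benzo_gt_4w,7,195,3.6,1,6.2
first_gen_antihistamine_first_line_gt7d,4,195,2.1,0.1,4
zdrug_gt_4w,3,195,1.5,0,3.3
nsaid_gt_3m,3,195,1.5,0,3.3
tca_first_line,2,195,1,0,2.4
dup_opioids,9,195,4.6,1.7,7.6
dup_benzodiazepines,3,195,1.5,0,3.3
dup_nsaids,1,195,0.5,0,1.5
dup_stimulant_laxatives,0,195,0,0,0
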