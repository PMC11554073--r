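parameter,level,kps_lt70,kps_ge70,reported_p
laterality,right,27,48,0.47
laterality,left,28,35,
laterality,bilateral,6,6,
extent_of_resection,1-49%,22,8,<0.001
extent_of_resection,50-89%,12,9,
extent_of_resection,90-99%,10,33,
extent_of_resection,100%,17,39,
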