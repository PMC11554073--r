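parameter,yes_kps_lt70,n_kps_lt70,yes_kps_ge70,n_kps_ge70,reported_p
sex,24,61,41,89,0.50
dominant_hand,58,61,89,89,0.07
epilepsy,12,61,28,89,0.13
aphasia,24,61,18,89,0.02
paralysis,35,61,32,89,0.01
other_neuro,45,61,57,89,0.22
surgery_biopsy,20,61,7,89,<0.001
awake_surgery,19,61,35,89,0.39
five_ala,25,61,53,89,0.03
pdt,1,61,6,89,0.24
carmustine,9,61,27,89,0.03
tmz,56,61,86,89,0.27
bevacizumab,32,61,33,89,0.068
mgmt_methylation,19,61,32,89,0.60
tertp,19,61,30,89,0.86
mgmt_ihc,20,61,34,89,0.60
ependymal_invasion,51,61,56,89,0.006
midline_shift,29,61,34,89,0.31
corpus_callosum_invasion,24,61,17,89,0.009
necrosis_cyst,58,61,80,89,0.36
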