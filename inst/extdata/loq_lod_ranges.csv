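compound,loq_min_ng_per_g,loq_max_ng_per_g,lod_min_ng_per_g,lod_max_ng_per_g
atenolol,2.4,7.9,0.80,2.6
carbamazepine,2.2,15,0.73,5.0
epoxide_cbz,1.2,13,0.40,4.3
dihydro_cbz,4.6,14,1.5,4.7
dihydro_dihydroxy_cbz,2.8,17,0.93,5.7
citalopram,4.2,7.1,1.4,2.4
clarithromycin,4.6,27,1.5,9.0
clindamycin,2.3,6.9,0.77,2.3
clindamycin_sulfoxide,1.8,11,0.60,3.7
fexofenadine,2.3,14,0.77,4.7
irbesartan,4.1,7.5,1.4,2.5
metoprolol,3.3,9.9,1.1,3.3
metoprolol_acid,1.9,9.6,0.63,3.2
n1_acetyl_sul,8.1,27,2.7,9.0
n4_acetyl_sul,7.6,21,2.5,7.0
n_desmethyl_cit,3.4,7.3,1.1,2.4
oxcarbazepine,5.7,14,1.9,4.7
sulfamethoxazole,6.7,14,2.2,4.7
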