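compound,solvent,recovery,rsd
atenolol,A,110,9
atenolol,B,112,4
atenolol,C,105,1
atenolol,D,99,2
carbamazepine,A,101,8
carbamazepine,B,94,1
carbamazepine,C,104,0
carbamazepine,D,98,1
epoxide_cbz,A,104,12
epoxide_cbz,B,76,6
epoxide_cbz,C,131,5
epoxide_cbz,D,103,2
dihydro_cbz,A,110,8
dihydro_cbz,B,98,3
dihydro_cbz,C,110,2
dihydro_cbz,D,106,4
dihydro_dihydroxy_cbz,A,85,10
dihydro_dihydroxy_cbz,B,127,13
dihydro_dihydroxy_cbz,C,102,14
dihydro_dihydroxy_cbz,D,88,9
citalopram,A,102,7
citalopram,B,97,2
citalopram,C,99,3
citalopram,D,94,2
clarithromycin,A,109,10
clarithromycin,B,108,1
clarithromycin,C,96,1
clarithromycin,D,96,2
clindamycin,A,107,8
clindamycin,B,86,4
clindamycin,C,121,6
clindamycin,D,116,3
clindamycin_sulfoxide,A,84,9
clindamycin_sulfoxide,B,82,5
clindamycin_sulfoxide,C,84,3
clindamycin_sulfoxide,D,86,3
fexofenadine,A,90,5
fexofenadine,B,85,3
fexofenadine,C,103,1
fexofenadine,D,97,0
irbesartan,A,91,7
irbesartan,B,112,4
irbesartan,C,97,2
irbesartan,D,98,2
metoprolol,A,110,8
metoprolol,B,94,2
metoprolol,C,103,2
metoprolol,D,99,2
metoprolol_acid,A,99,8
metoprolol_acid,B,79,5
metoprolol_acid,C,96,2
metoprolol_acid,D,91,1
n1_acetyl_sul,A,137,11
n1_acetyl_sul,B,115,5
n1_acetyl_sul,C,90,11
n1_acetyl_sul,D,80,1
n4_acetyl_sul,A,102,4
n4_acetyl_sul,B,112,4
n4_acetyl_sul,C,96,4
n4_acetyl_sul,D,95,5
n_desmethyl_cit,A,88,6
n_desmethyl_cit,B,100,1
n_desmethyl_cit,C,96,3
n_desmethyl_cit,D,89,1
oxcarbazepine,A,91,10
oxcarbazepine,B,102,2
oxcarbazepine,C,93,2
oxcarbazepine,D,88,2
sulfamethoxazole,A,110,8
sulfamethoxazole,B,97,1
sulfamethoxazole,C,110,2
sulfamethoxazole,D,116,3
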