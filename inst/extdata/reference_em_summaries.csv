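condition,n_stacks,mean_max_cisterna_length_nm,sem_max_cisterna_length_nm,mean_cisternae_count,sem_cisternae_count,mean_vesicles_within_1um,sem_vesicles_within_1um
Control,11,896.3,120.9,4.0,0.2,6.7,1.1
ZW10,22,419.3,37.3,3.4,0.2,18.9,2.0
Rab6 (Sun),5,2911.6,394.4,5.6,0.2,57.6,12.5
Rab6 (Young),7,2718.6,340.0,5.4,0.2,82.4,7.6
Rab6A,8,1577.5,197.1,3.9,0.1,32.8,3.4
Rab6A',7,1743.9,209.0,4.4,0.2,44.0,5.9
Rab27A,11,1007.9,131.6,3.5,0.2,30.5,3.9
Rab33B,10,1065.3,144.9,3.7,0.3,32.1,3.9
Kif25,12,1023.2,186.8,3.8,0.2,33.1,5.9
KifC3,9,971.1,169.9,3.7,0.2,26.8,4.7
COG3+Rab6 (Sun),10,1515.7,361.4,3.8,0.3,36.9,6.4
ZW10+Rab6 (Sun),13,856.2,85.1,4.8,0.5,34.5,4.1
ZW10+Rab27A,9,785.6,184.8,3.7,0.2,29.4,2.9
ZW10+Rab33B,12,865.1,115.4,3.9,0.2,22.7,4.1
ZW10+Kif25,15,833.5,141.5,3.7,0.2,21.3,2.5
ZW10+KifC3,9,831.0,87.7,3.8,0.3,25.3,3.1
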