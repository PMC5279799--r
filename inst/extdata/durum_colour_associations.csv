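trait,hap_locus,nbM,hap_r2,hap_effect,snp,snp_r2,snp_effect,ive_printed,iae_printed
pasta_a,hap_4B_6,9,35.7,1.6,Tdurum_contig51688_681,19.0,1.6,87.9,0.0
pasta_b,hap_2A_5,4,16.4,3.3,Tdurum_contig54634_815,9.5,3.2,72.6,3.1
pasta_b,hap_4B_6,9,40.2,5.6,Tdurum_contig51688_681,26.2,5.3,53.4,5.7
pasta_b,hap_4B_12,6,14.1,4.5,Tdurum_contig37811_134,10.9,3.4,29.4,32.4
pigment_loss,hap_2A_5,4,17.6,3.5,Tdurum_contig54634_815,11.9,2.4,47.9,79.2
pigment_loss,hap_4B_6,9,33.6,3.7,Tdurum_contig51688_681,26.2,3.7,28.2,27.0
pigment_loss,hap_4B_12,6,17.5,3.3,Tdurum_contig37811_134,13.0,2.6,34.6,26.9
semolina_b,hap_2A_18,9,24.5,2.5,BobWhite_c41527_201,19.2,1.9,27.6,31.6
semolina_b,hap_7A_32,10,34.6,3.3,Tdurum_contig54832_139,19.8,2.0,74.7,65.0
semolina_pigment,hap_2A_18,9,27.5,1.9,BobWhite_c41527_201,21.4,1.4,28.5,35.7
semolina_pigment,hap_7A_32,10,35.6,2.3,Tdurum_contig54832_139,21.0,1.4,69.5,64.3
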