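"method","published_rank","published_s","published_sigma_rank","rank_dice_GM","rank_h95_GM","rank_avd_GM","rank_dice_WM","rank_h95_WM","rank_avd_WM","rank_dice_CSF","rank_h95_CSF","rank_avd_CSF","rank_dice_brain","rank_h95_brain","rank_avd_brain","rank_dice_ICV","rank_h95_ICV","rank_avd_ICV","mu_dice_GM","mu_h95_GM","mu_avd_GM","mu_dice_WM","mu_h95_WM","mu_avd_WM","mu_dice_CSF","mu_h95_CSF","mu_avd_CSF","mu_dice_brain","mu_h95_brain","mu_avd_brain","mu_dice_ICV","mu_h95_ICV","mu_avd_ICV","sigma_dice_GM","sigma_h95_GM","sigma_avd_GM","sigma_dice_WM","sigma_h95_WM","sigma_avd_WM","sigma_dice_CSF","sigma_h95_CSF","sigma_avd_CSF","sigma_dice_brain","sigma_h95_brain","sigma_avd_brain","sigma_dice_ICV","sigma_h95_ICV","sigma_avd_ICV"
"BIGR2",1,38,4,1,2,4,2,2,4,4,5,14,1,2,12,8,4,12,84.7,1.9,6.1,88.4,2.4,6,78.3,3.2,23,95.1,2.7,3.2,96,3.9,5.2,1.3,0.4,3.3,1.2,0.5,5.1,5,0.8,17,0.5,0.8,1.6,1.3,1.1,3
"UofL BioImaging",2,38,8,5,1,9,4,1,13,2,2,1,2,1,12,5,2,5,83,1.7,8.6,87.9,2.2,8.7,78.9,2.7,9.7,94.9,2.4,3.9,96.7,3.4,1.8,1.5,0.3,5.4,2,0.6,6.6,4.2,0.5,10,0.6,0.5,2,0.8,0.6,2
"CMIV",3,50,,6,7,5,5,3,10,3,3,8,5,7,2,4,3,11,82.4,2.7,6.8,87.7,2.4,7.3,78.6,3,14,94.5,3.8,2.6,96.8,3.8,4.9,1.4,0.4,4,1.6,0.4,3.8,3.1,0.4,5.9,0.5,1.1,2.2,0.8,1.3,2.3
"UB VPML Med",4,61,,4,4,2,1,5,7,8,13,17,4,4,1,10,11,15,83.3,2.1,5.9,88.6,2.7,7.1,74.8,4.3,31,94.6,2.8,2.4,94.8,6.6,7.7,1.3,0.3,5.3,1.7,0.4,3.8,7.1,1.7,19,0.6,0.4,1.8,2,2,4.1
"Bigr_neuro",5,64,,7,13,3,6,6,9,6,4,10,7,10,10,7,5,8,81.5,3.7,5.9,87.3,3,7.3,78.2,3.2,16,94,4.6,3.6,96.3,3.9,3.5,1.7,0.9,4.2,1.4,0.4,3.8,4.7,0.6,14,0.8,1.4,2.4,1.2,0.9,2.7
"Robarts",6,66,,11,3,15,8,8,6,1,1,13,16,3,18,1,1,1,79.7,2,9.8,86.2,3.1,7.1,80.3,2.7,20,93.1,2.8,7.9,97.9,2.6,0.9,2.4,0.1,7.3,1.3,0.4,6.2,4.1,0.5,13,1.6,0.5,3.6,0.3,0.4,0.7
"Narsil",7,71,,3,5,1,7,11,2,17,18,7,3,5,3,16,18,9,83.5,2.3,5.5,87.1,3.3,5.8,66.6,13.3,14,94.8,2.9,2.9,92.5,24,3.7,1.8,0.4,4.4,1.3,0.9,5.3,2.4,5.4,9.5,0.5,0.5,2,0.5,8.9,1.7
"SPM_T1_F",8,75,,8,9,16,9,7,1,9,14,2,9,14,14,6,14,4,81.2,2.9,10,86,3,5.2,74.1,4.6,10,93.9,5.8,5.3,96.6,8.2,1.5,2.2,0.3,8.5,1.5,0.1,3.8,3.4,0.6,4.7,1,2.2,3.8,0.2,3,1
"SPM_T1_IR",9,81,,12,11,7,16,12,5,5,10,3,8,11,7,2,8,2,79.4,3,7.2,83.5,3.6,6.3,78.3,4,10,93.9,4.6,3.4,97.7,6.5,1,2.1,0.4,6.3,2.1,0.3,4.6,3.8,0.6,5.7,0.8,1.2,2.8,0.2,1.3,0.8
"MNAB",10,86,,2,8,12,3,4,11,15,15,16,6,9,11,15,12,17,83.9,2.8,9.1,88,2.7,7.8,68.1,4.9,29,94.5,4.5,3.8,92.5,7.1,9.7,2.1,0.9,6.5,1.2,0.8,4,4,2.2,21,1,2,3.2,1.1,4.2,4.7
"SPM_T1",11,91,,9,10,6,11,10,3,11,16,15,10,8,6,9,13,13,80.3,3,6.9,85.6,3.1,6,70.7,5.3,23,93.9,4.4,3.2,95.3,8.1,5.5,2.4,0.5,6.8,1.7,0.1,4.1,3.8,1.5,15.7,0.9,1.6,2.9,0.9,3.7,3.7
"FSL_Seg",12,99,,13,16,10,10,13,14,12,6,5,13,13,4,12,6,6,78.7,4.3,8.6,86,3.7,11.5,69.9,3.4,12,93.3,5.5,3,94.2,5.3,3.4,2.2,1.2,6.3,2.6,0.8,6.3,2.8,0.2,10.3,0.8,1.4,1.5,0.8,1.1,1.5
"SPM_T1_IR_F",13,105,,10,12,18,15,14,12,7,11,6,12,15,13,3,15,3,80.1,3,13.9,83.6,3.8,8.4,76.9,4.1,12,93.6,5.9,5.1,97.7,8.2,1.2,2.4,0.2,9.6,2.1,0.5,5.2,3.1,0.5,6,1.1,1.8,3.6,0.2,1.8,0.9
"FSL_PVSeg",14,107,,15,15,8,13,15,17,13,7,4,11,16,9,13,7,7,77.7,4.3,8.4,84.8,3.8,19.7,69.5,3.4,11,93.6,6.1,3.5,94.2,5.3,3.4,2.6,1.3,6.5,3.2,0.9,10,2.2,0.3,5.8,0.9,1.6,3,0.8,1.1,1.5
"FreeSurfer",15,116,13,16,6,17,12,9,8,18,12,18,17,6,16,17,10,18,77.4,2.3,12.1,85.2,3.1,7.2,65.8,4.3,50,92.3,3.6,6.3,92.4,6.6,10,2,0.6,6,2.2,0.5,4.6,3.7,0.6,19.6,0.8,0.6,3.4,0.9,0.4,4.5
"Jedi Mind Meld",16,116,17,14,14,11,17,16,15,10,8,11,15,12,8,11,16,14,77.8,3.9,8.9,80.6,4.5,13.7,73.3,3.7,18,93.2,5.4,3.5,94.3,20,6.8,5.9,2.8,7.6,9.6,3.6,12,3.5,0.8,9,1.7,4.8,3,1.7,3.7,3.1
"S2_QM",17,130,,17,17,13,14,17,18,16,9,9,14,17,15,14,9,10,76.4,5.5,9.3,83.9,4.9,24.8,67.9,3.8,14,93.3,7,5.5,93.7,6.5,4,3.4,3,6.4,3.4,3.2,10,2.3,0.6,9.9,1.4,3.5,4.5,1.1,1.4,2.2
"LNMBrains",18,145,,18,18,14,18,18,16,14,17,12,18,18,17,18,17,16,72.8,6.8,9.5,78.3,6.8,15.3,68.8,7.7,20,88.5,8.6,7.4,89.2,20.4,7.9,5.3,2.3,7.6,6.4,3.5,13,6.6,2.4,13,4.5,2.8,7.7,4.8,3.7,8.3
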