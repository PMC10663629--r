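id,diagnosis,sex,age,etiology,delay_days,crs_auditory,crs_visual,crs_motor,crs_oromotor,crs_communication,crs_arousal,drugs_pupil,mechanical_ventilation,startle,erp_quality,erp_sound,erp_mve,erp_local,erp_global,pdr_quality,pdr_sound,pdr_mve,pdr_local,pdr_global,outcome_6m
1,VS/UWS,M,43,Anoxia,33,0,0,1,1,0,1,No,Yes,No,poor,NA,NA,NA,NA,correct,significant,significant,ns,ns,Death
2,VS/UWS,F,73,Anoxia,30,0,0,2,0,0,1,No,Yes,No,poor,NA,NA,NA,NA,correct,significant,ns,ns,ns,Death
3,VS/UWS,F,36,Stroke,104,1,2,2,1,0,1,No,Yes,Yes,correct,significant,significant,significant,ns,correct,significant,ns,ns,ns,Conscious
4,VS/UWS,F,38,TBI,45,1,1,2,1,0,2,Scopolamine,Yes,Yes,poor,significant,significant,significant,ns,correct,significant,ns,ns,ns,Death
5,VS/UWS,M,28,Anoxia,34,2,0,2,1,0,1,No,Yes,Yes,correct,significant,ns,ns,ns,correct,significant,ns,ns,ns,Death
6,VS/UWS,M,62,SAH,46,1,1,2,1,0,1,No,Yes,Yes,correct,significant,significant,ns,ns,correct,significant,ns,ns,ns,MCS+
7,VS/UWS,F,51,Anoxia,724,1,1,1,1,0,1,Scopolamine,No,Yes,poor,significant,significant,significant,ns,poor,significant,ns,ns,ns,VS/UWS
8,VS/UWS,M,26,Anoxia,67,1,0,1,2,0,1,Phenobarbital,No,Yes,correct,significant,ns,ns,ns,poor,significant,ns,ns,ns,VS/UWS
9,VS/UWS,F,36,Anoxia,27,0,0,2,1,0,2,No,Yes,No,correct,significant,significant,significant,ns,correct,ns,ns,ns,ns,VS/UWS
10,VS/UWS,F,63,ICH,49,0,0,2,1,0,2,No,Yes,No,correct,significant,ns,significant,ns,correct,significant,ns,ns,ns,Death
11,MCS,F,56,SAH,188,1,3,2,1,0,2,Propericiazine,No,Yes,correct,significant,significant,significant,ns,correct,significant,ns,ns,ns,NA
12,MCS,M,63,Stroke,89,0,3,0,0,0,2,No,Yes,No,correct,significant,significant,ns,significant,correct,ns,ns,ns,ns,Death
13,MCS,M,17,Hypoglycemia,242,1,3,2,1,0,2,No,No,Yes,correct,significant,significant,significant,significant,poor,significant,ns,trend,ns,Death
14,MCS,F,56,TBI,37,2,3,2,1,0,2,Venlafaxine,Yes,Yes,poor,significant,significant,significant,ns,correct,significant,ns,ns,ns,Death
15,MCS,F,38,TBI,45,1,3,2,1,0,1,No,No,Yes,poor,significant,significant,significant,ns,correct,significant,significant,ns,ns,Death
16,MCS,M,44,TBI,1215,1,3,2,2,0,2,"Ipratropium, scopolamine",No,Yes,poor,significant,ns,ns,ns,correct,significant,ns,ns,ns,MCS-
17,MCS,M,29,Anoxia,35,2,3,2,2,0,2,Paroxetine,Yes,Yes,poor,significant,significant,significant,ns,poor,significant,ns,ns,ns,MCS-
18,MCS,M,19,TBI,49,0,0,5,1,0,2,No,No,No,poor,significant,significant,significant,ns,correct,significant,trend,ns,trend,Conscious
19,MCS,F,22,Anoxia,418,1,3,1,1,0,3,No,No,Yes,poor,significant,ns,significant,ns,poor,significant,significant,ns,ns,MCS-
20,MCS,M,76,Epilepsy,12,3,5,2,2,1,1,Phenobarbital,Yes,Yes,correct,significant,significant,significant,ns,correct,significant,significant,ns,ns,Conscious
21,MCS,F,43,SAH,69,4,5,0,1,1,3,Scopolamine,No,Yes,correct,significant,significant,significant,significant,poor,significant,ns,ns,ns,Conscious
22,MCS,F,19,TBI,31,3,3,4,2,0,2,No,Yes,Yes,correct,significant,significant,ns,significant,correct,significant,trend,ns,ns,Conscious
23,MCS,M,49,ICH,41,2,3,3,2,1,2,No,No,Yes,correct,significant,ns,ns,ns,correct,significant,ns,ns,ns,Conscious
24,MCS,M,54,Stroke,498,3,4,5,2,1,3,"Scopolamine, tramadol",No,Yes,correct,significant,significant,significant,significant,correct,significant,significant,ns,significant,Conscious
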