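covariate,level,n_nonuser,n_user
education,no_education,596,535
education,primary,2233,2592
education,secondary,329,379
education,tertiary,79,104
working,yes,2755,3183
working,no,481,426
radio,yes,1666,2100
radio,no,1571,1509
newspapers,yes,150,265
newspapers,no,3086,3344
tv,yes,195,294
tv,no,3042,3314
religion,catholic,1129,1489
religion,protestant,1637,1482
religion,adventist,361,517
religion,other,103,118
fp_worker_visit,yes,813,1184
fp_worker_visit,no,2424,2426
health_facility_visit,yes,2379,2539
health_facility_visit,no,858,1071
wealth,poorest,667,622
wealth,poorer,730,719
wealth,middle,654,774
wealth,richer,599,760
wealth,richest,586,735
residence,urban,516,648
residence,rural,2720,2962
husband_desires,same,430,398
husband_desires,more,1886,2261
husband_desires,fewer,563,660
husband_desires,do_not_know,358,290
husband_education,no_education,601,558
husband_education,primary,2222,2579
husband_education,secondary,295,333
husband_education,tertiary,111,132
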