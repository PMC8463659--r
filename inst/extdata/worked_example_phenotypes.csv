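"sample_id","group","age","bmi","mmse","abeta42","ttau","ptau181","apoe","smoke","race","abeta_ttau","abeta_ptau","ptau_ttau"
"WX01","ComC",30,24,30,320,40,27,"e3/e3","no","White",8,11.8518518518519,0.675
"WX02","ComC",35,25,30,310,42,28,"e3/e4","no","White",7.38095238095238,11.0714285714286,0.666666666666667
"WX03","ComC",40,26,29,330,38,26,"e3/e3","yes","Asian/PI",8.68421052631579,12.6923076923077,0.684210526315789
"WX04","DepC",32,27,30,300,36,30,"e3/e3","no","White",8.33333333333333,10,0.833333333333333
"WX05","DepC",38,26,29,315,35,29,"e3/e4","no","Black",9,10.8620689655172,0.828571428571429
"WX06","DepTBI",31,28,29,305,37,28,"e4/e4","yes","White",8.24324324324324,10.8928571428571,0.756756756756757
"WX07","DepTBI",36,29,28,325,39,27,"e3/e3","no","White",8.33333333333333,12.037037037037,0.692307692307692
"WX08","DepTBI",41,30,29,312,41,30,"e3/e4","no","Other",7.60975609756098,10.4,0.731707317073171
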