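"age_low","age_high","measure","stage","rate","weight"
30,34,"incidence","I",0.0283000528203054,1
30,34,"incidence","II",0.00710968088759412,1
30,34,"incidence","III",0,1
30,34,"incidence","IV",0,1
30,34,"mortality",,6.3515788781022e-05,1
35,39,"incidence","I",0.717522672025737,1
35,39,"incidence","II",0.639836526209859,1
35,39,"incidence","III",0.312364136308965,1
35,39,"incidence","IV",0.151209552393891,1
35,39,"mortality",,0.108401896015276,1
40,44,"incidence","I",2.71347292223586,1
40,44,"incidence","II",3.14442789385395,1
40,44,"incidence","III",2.02400246785311,1
40,44,"incidence","IV",1.44209723915156,1
40,44,"mortality",,1.54378919709632,1
45,49,"incidence","I",5.97771554845742,1
45,49,"incidence","II",7.63046764155498,1
45,49,"incidence","III",5.37938010653362,1
45,49,"incidence","IV",4.32037636301906,1
45,49,"mortality",,5.72650846863904,1
50,54,"incidence","I",10.4408756392225,1
50,54,"incidence","II",13.9779737975036,1
50,54,"incidence","III",10.2770231386985,1
50,54,"incidence","IV",8.69853757540316,1
50,54,"mortality",,12.9056979925629,1
55,59,"incidence","I",16.0749510739642,1
55,59,"incidence","II",22.1262732031497,1
55,59,"incidence","III",16.6559789068884,1
55,59,"incidence","IV",14.5061879883582,1
55,59,"mortality",,23.0163377881125,1
60,64,"incidence","I",22.8794934931695,1
60,64,"incidence","II",32.0622209329066,1
60,64,"incidence","III",24.4972324332513,1
60,64,"incidence","IV",21.7157763714718,1
60,64,"mortality",,36.0123383872032,1
65,69,"incidence","I",30.857471502068,1
65,69,"incidence","II",43.7849927045794,1
65,69,"incidence","III",33.7960551222807,1
65,69,"incidence","IV",30.3176901362352,1
65,69,"mortality",,51.9033216686089,1
70,74,"incidence","I",39.9772793179087,1
70,74,"incidence","II",57.2504811791091,1
70,74,"incidence","III",44.5179792247406,1
70,74,"incidence","IV",40.2795546151266,1
70,74,"mortality",,70.7217690906985,1
75,79,"incidence","I",50.1095274263758,1
75,79,"incidence","II",72.2785305895214,1
75,79,"incidence","III",56.5252391889024,1
75,79,"incidence","IV",51.4781549098867,1
75,79,"mortality",,92.4456348652721,1
80,84,"incidence","I",60.9219875740421,1
80,84,"incidence","II",88.3977514397825,1
80,84,"incidence","III",69.4531707512041,1
80,84,"incidence","IV",63.5845561784177,1
80,84,"mortality",,116.860372116214,1
85,89,"incidence","I",71.702975709826,1
85,89,"incidence","II",104.582375038666,1
85,89,"incidence","III",82.4993427152706,1
85,89,"incidence","IV",75.8668980121302,1
85,89,"mortality",,143.307965282011,1
90,94,"incidence","I",81.068988487164,1
90,94,"incidence","II",118.812333976216,1
90,94,"incidence","III",94.0685282983371,1
90,94,"incidence","IV",86.8559274931959,1
90,94,"mortality",,170.21551848295,1
95,99,"incidence","I",86.487508609286,1
95,99,"incidence","II",127.347449483129,1
95,99,"incidence","III",101.182398550563,1
95,99,"incidence","IV",93.7843746702506,1
95,99,"mortality",,194.143807408226,1
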