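age,sex,height,bmi,asa_ps,cci,hypertension,coronary_artery_disease,diabetes,stroke_tia,isced,mmse,cognitive_impairment,adl_impaired,iadl_impaired,mna,frailty,gds,benzodiazepine_use,hazardous_alcohol,smoker,pack_years,surgery_site,anesthesia_duration,premedication,pod
73,0,170,33.2,2,1,1,,0,0,3,29,0,0,0,3,0,4,0,0,0,6,3,311,0,1
69,0,181,,2,4,1,0,0,0,8,25,0,1,0,3,0,2,0,0,1,10,2,90,0,0
66,0,172,30.1,3,0,1,0,0,0,5,28,1,0,,3,1,1,0,0,0,0,2,232,,0
83,1,153,21.6,2,2,1,0,0,0,6,29,0,0,0,3,1,2,0,0,0,6,3,725,0,0
75,0,175,28.8,3,0,1,0,0,1,2,29,0,0,0,3,1,0,0,0,0,37,3,92,0,0
75,1,161,17.5,2,8,1,0,0,0,4,30,1,1,0,2,0,2,0,0,1,0,2,74,0,0
65,1,175,27.2,2,2,0,0,0,0,7,27,1,0,0,3,1,1,0,0,1,0,2,99,1,0
83,1,169,30.2,1,2,1,1,0,0,7,28,1,0,0,3,1,0,0,0,0,4,3,263,0,0
65,0,186,33.4,3,3,0,0,0,0,8,,0,0,0,,0,3,1,1,0,31,3,470,0,1
74,0,171,37.4,2,0,0,0,1,0,7,29,0,1,0,3,2,2,0,0,0,0,2,210,1,0
79,1,164,26,2,0,0,0,0,0,3,,0,0,1,3,1,2,0,0,0,0,2,262,0,1
80,0,173,17.3,3,0,1,0,,0,5,30,1,0,0,3,2,2,0,0,0,,2,201,1,1
74,1,162,18.1,3,0,1,0,0,0,,30,0,0,0,3,0,1,0,0,0,38,3,177,0,0
70,0,170,25.9,2,0,1,0,0,0,7,24,,0,0,3,,5,0,0,0,7,2,330,0,0
78,0,163,29.5,3,0,0,0,0,0,3,27,0,0,0,3,1,0,1,0,0,0,3,171,0,0
73,1,177,28.5,3,0,1,0,0,,4,29,0,,,,2,2,0,1,0,0,2,,1,1
71,0,160,28.6,1,1,1,0,1,0,5,27,,0,0,2,,0,0,0,0,4,2,239,0,0
,0,155,,3,2,1,0,1,1,4,25,0,1,0,3,1,3,0,0,0,0,2,358,0,1
74,1,163,17.6,2,3,0,0,1,0,5,29,0,0,0,3,0,1,0,,1,14,1,95,1,0
74,0,177,27.6,2,4,1,0,0,0,4,26,0,0,0,3,0,4,0,0,0,27,2,76,0,0
65,0,156,31.3,3,7,0,0,0,1,7,27,,0,0,3,1,3,0,0,0,0,2,540,,0
76,0,172,24.9,3,0,0,0,1,0,4,27,0,0,,3,1,2,0,0,0,10,3,70,0,0
71,0,177,,2,2,1,0,1,0,7,26,0,1,0,3,,2,0,0,0,0,3,116,0,0
74,0,157,26.1,3,1,0,0,0,0,6,,0,0,0,3,1,2,0,0,0,0,2,359,0,1
77,1,167,27.7,2,4,1,0,0,0,5,29,0,0,0,3,2,5,0,0,0,11,,,1,1
75,0,181,37.2,2,0,1,0,0,0,3,28,0,0,0,2,0,0,0,0,0,3,2,276,0,0
65,1,178,26.8,2,,0,0,1,1,6,30,0,0,0,3,1,2,0,,,5,,141,0,0
70,0,160,23.8,1,2,,,0,,7,29,0,0,0,3,1,0,0,0,0,0,2,325,0,1
71,0,169,27.3,,0,1,1,1,0,3,30,0,0,0,3,1,3,0,1,0,20,2,163,1,0
69,1,163,25.2,2,3,1,1,0,0,6,27,0,0,0,3,1,3,0,0,,0,3,207,1,0
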