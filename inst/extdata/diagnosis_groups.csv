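id,name,care_class,annual_cost_meur,n_patients,vo_category,max_travel_min,in_model
1,Acute infectious and parasitic diseases and poisoning,acute,95.8,93193,intermediate,45,TRUE
2,Chronic infectious and parasitic diseases,chronic,184.4,3885,high,120,TRUE
3,Neoplasms,chronic,1845.1,405124,high,120,TRUE
4,Diabetes,chronic,197.6,17445,none,45,TRUE
5,Endocrine metabolic and immunity disorders,chronic,220,46837,intermediate,45,TRUE
6,Haematology,mixed,146.1,51064,high,45,TRUE
7,Acute mental disorders,acute,85.7,12000,high,45,TRUE
8,Chronic mental disorders,chronic,306.6,22134,none,45,TRUE
9,Diseases of the nervous system,chronic,522.2,89335,low,45,TRUE
10,Eyecare,elective,596.9,207327,low,45,TRUE
11,Earcare,elective,230.4,61090,intermediate,45,TRUE
12,Cerebral hemorrhage and ischemia,acute,436.3,47925,high,45,TRUE
13,Chronic cardiovascular disease,chronic,938.5,180186,none,45,TRUE
14,Cardiovascular disease with intervention,acute,1047.7,163275,high,45,TRUE
15,Acute diseases of the respiratory system,acute,246.7,64310,low,45,TRUE
16,Complex pulmonary surgery,elective,305.6,20502,high,45,TRUE
17,Common surgery of the respiratory system,elective,122.1,74168,low,45,TRUE
18,Chronic obstructive pulmonary disease and allied conditions,chronic,305.5,48236,none,120,TRUE
19,Surgery of diseases of the digestive system,elective,422.7,215757,intermediate,45,TRUE
20,Diseases of oral cavity salivary glands and jaws,chronic,1108.9,26366,low,45,TRUE
21,Gynaecology,elective,481.6,82053,low,45,TRUE
22,Urinary system,elective,497.1,151334,low,45,TRUE
23,Complications of pregnancy childbirth and the puerperium,elective,739.3,296513,intermediate,45,TRUE
24,Dermatology,chronic,412.3,68625,low,45,TRUE
25,Rheumatism and arthropathies non surgical,chronic,961.2,157265,low,45,TRUE
26,Diseases of the musculoskeletal system requiring surgical treatment,elective,857.3,238155,intermediate,45,TRUE
27,Congenital disorders,chronic,216.1,25669,high,120,TRUE
28,Conditions originating in the perinatal period,elective,331.2,75980,high,120,TRUE
29,Signs symptoms and ill-defined conditions,NA,2746.3,346106,intermediate,45,FALSE
30,Emergency care,acute,604.1,52605,none,45,TRUE
31,Specialized trauma care,acute,475.6,77330,high,120,TRUE
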