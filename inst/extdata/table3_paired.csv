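"country","p_low","cluster_low","se_low","p_high","cluster_high","se_high","chi2","chi2_p","diff_printed","se_diff_printed","z_printed","aggregate"
"Austria",57.2,"L-3",2.42,50.2,"L-1",0.86,0.18,0.67,-7,2.4,-2.89,FALSE
"Belgium",49.9,"L-2",1.94,41.8,"L-2",0.62,0.33,0.57,-8,2,-43,FALSE
"Chile",62.9,"L-3",2.34,55.2,"L-1",0.77,0.2,0.65,-8,2.5,-39,FALSE
"France",51.3,"L-2",2.21,46.5,"L-2",0.8,0.08,0.78,-5,2.4,-1.98,FALSE
"Germany",43.1,"L-1",4.17,41.1,"L-2",0.75,0,0.95,-2,4.4,-0.45,FALSE
"Greece",65.5,"H-1",2.48,58.5,"H-2",0.71,0.14,0.7,-7,2.5,-2.75,FALSE
"Hungary",61.5,"L-3",3.1,54.2,"L-1",0.83,0.16,0.68,-7,3,-2.41,FALSE
"Israel",52.2,"L-2",2.53,43.5,"L-2",0.73,0.39,0.53,-9,2.6,-3.39,FALSE
"Korea",59.4,"L-3",1.9,54.7,"L-1",0.79,0.05,0.81,-5,1.9,-2.43,FALSE
"Mexico",66.1,"H-1",2.8,59.4,"H-2",0.82,0.13,0.72,-7,2.9,-2.32,FALSE
"Turkey",63.2,"L-3",2.32,58.1,"H-2",0.87,0.06,0.8,-5,2.5,-25,FALSE
"United States",75.7,"H-2",2.38,67.1,"H-2",0.69,0.19,0.65,-9,2.4,-3.64,FALSE
"Croatia",55.9,"L-3",2.77,46.5,"L-2",0.86,0.4,0.52,-9,2.7,-3.46,FALSE
"Russia",40.6,"L-1",4.4,51.5,"L-1",0.8,0.66,0.41,11,4.2,2.57,FALSE
"United Arab Emirates",58.2,"L-3",1.21,62.7,"H-2",0.7,0.43,0.83,4,1.3,3.57,FALSE
"OECD average",57.7,"",0.51,54.8,"",0.13,0.01,0.91,-3,0.5,-5.48,TRUE
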