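"pair_id","zygosity","attainment_1","attainment_2","performance_1","performance_2","tracking_1","tracking_2","male_1","male_2","birth_year_1","birth_year_2"
"P00001","MZ",3.42,3.4,541.5,544.3,,"delayed",1,1,1992,1992
"P00002","MZ",2.12,,535.8,535.9,"immediate","immediate",0,0,1992,1992
"P00003","MZ",1.85,2.94,537.4,532.8,,,1,1,1986,1986
"P00004","MZ",2.9,3.13,540.2,543,,"delayed",1,1,1996,1996
"P00005","MZ",3.87,,558.1,547.9,,"immediate",1,1,1987,1987
"P00006","MZ",3.82,,550,549.3,"delayed",,1,1,1999,1999
"P00007","DZ",2.42,2.18,538.8,534.1,"delayed","delayed",1,1,1992,1992
"P00008","DZ",,,526.9,528.1,,"immediate",0,1,1989,1989
"P00009","DZ",2.5,,535.2,538.4,"delayed","delayed",1,0,1998,1998
"P00010","DZ",3.12,2.16,538.7,543.4,"immediate",,1,1,1997,1997
"P00011","DZ",2.82,,536.5,527.7,"immediate","immediate",1,0,1988,1988
"P00012","DZ",2.66,3.15,536.2,538.3,"immediate","immediate",0,0,1997,1997
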