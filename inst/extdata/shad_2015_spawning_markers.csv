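date,site,n_females,p_day_minus1,p_day0,p_day_plus1,p_day_plus2,sf,si
2015-05-12,H,28,0.61,0.11,0.00,0.18,0.22,4.54
2015-05-13,C,30,0.57,0.20,0.13,0.37,0.32,3.13
2015-05-19,H,29,0.41,0.38,0.00,0.03,0.21,4.76
2015-05-20,V,32,0.50,0.34,0.03,0.75,0.41,2.44
2015-05-26,H,33,0.21,0.36,0.03,0.03,0.16,6.25
2015-05-27,C,32,0.28,0.34,0.00,0.22,0.21,4.76
2015-06-02,H,27,0.44,0.19,0.04,0.07,0.19,5.26
2015-06-03,V,5,0.60,0.20,0.00,0.20,0.25,4.00
2015-06-09,H,28,0.46,0.11,0.00,0.07,0.16,6.25
2015-06-10,C,16,0.19,0.44,0.00,0.13,0.19,5.26
2015-06-16,H,32,0.16,0.34,0.00,0.03,0.13,7.69
2015-06-17,V,8,0.75,0.38,0.00,0.00,0.28,3.57
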