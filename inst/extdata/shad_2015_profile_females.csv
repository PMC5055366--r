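migration,location,maturity_class,date,fork_length_mm,age_yr,gsi,maos,pofs_present,panel
upstream,Lower River,A,2015-04-30,426,,21.5,NM2,FALSE,A
upstream,Lower River,A,2015-04-30,467,5,16.4,NM1,FALSE,B
upstream,Lower River,A,2015-05-05,528,7,8.5,V2,FALSE,C
upstream,Vernon,A,2015-05-20,449,5,20.0,NM2,TRUE,D
upstream,Cabot,A,2015-06-10,401,3,27.1,NM2,FALSE,E
upstream,Hadley Falls,A,2015-05-19,503,6,23.7,NM1,FALSE,F
downstream,,E,2015-06-18,408,5,2.6,NM1,TRUE,A
downstream,,E,2015-06-18,426,5,3.2,NM1,TRUE,B
downstream,,E,2015-06-30,458,7,4.5,NM1,TRUE,C
downstream,,F,2015-06-18,423,5,1.9,V2,TRUE,D
downstream,,F,2015-06-30,422,4,1.7,V1,TRUE,E
downstream,,F,2015-06-30,417,5,1.5,PE,TRUE,F
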