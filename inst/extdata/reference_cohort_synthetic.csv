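id,stage,esr_elevated,bulk_present,extranodal,b_symptoms,protocol,tg_tl,response
P01,I,FALSE,FALSE,FALSE,FALSE,C1,1,IR
P02,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,IR
P03,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,IR
P04,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,IR
P05,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,IR
P06,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,IR
P07,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,AR
P08,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,AR
P09,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,AR
P10,IIA,FALSE,FALSE,FALSE,FALSE,C1,1,AR
P11,IIA,FALSE,FALSE,FALSE,FALSE,C2,1,AR
P12,IIA,FALSE,FALSE,FALSE,FALSE,C2,1,AR
P13,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P14,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P15,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P16,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P17,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P18,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P19,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P20,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P21,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P22,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,IR
P23,IIB,TRUE,FALSE,FALSE,TRUE,C1,2,AR
P24,IIB,TRUE,TRUE,FALSE,TRUE,C2,2,AR
P25,IIB,TRUE,TRUE,FALSE,TRUE,C2,2,AR
P26,IIIA,TRUE,FALSE,FALSE,FALSE,C1,2,AR
P27,IIIA,TRUE,FALSE,FALSE,FALSE,C1,2,AR
P28,IIIA,TRUE,FALSE,FALSE,FALSE,C1,2,AR
P29,IIIA,TRUE,TRUE,FALSE,FALSE,C1,2,AR
P30,IIB,TRUE,TRUE,TRUE,TRUE,C1,3,IR
P31,IIB,TRUE,TRUE,TRUE,TRUE,C1,3,IR
P32,IIIA,TRUE,FALSE,TRUE,FALSE,C1,3,IR
P33,IIIA,TRUE,FALSE,TRUE,FALSE,C1,3,IR
P34,IIIB,TRUE,TRUE,FALSE,TRUE,C2,3,IR
P35,IV,TRUE,FALSE,FALSE,TRUE,C1,3,IR
P36,IV,TRUE,FALSE,FALSE,TRUE,C1,3,IR
P37,IV,TRUE,FALSE,FALSE,TRUE,C1,3,IR
P38,IV,TRUE,FALSE,FALSE,TRUE,C1,3,IR
P39,IV,TRUE,FALSE,FALSE,TRUE,C1,3,IR
P40,IV,TRUE,FALSE,FALSE,TRUE,C1,3,IR
P41,IV,TRUE,FALSE,FALSE,TRUE,C1,3,IR
P42,IV,TRUE,FALSE,FALSE,TRUE,C1,3,AR
P43,IV,TRUE,FALSE,FALSE,TRUE,C1,3,AR
P44,IV,TRUE,FALSE,FALSE,TRUE,C1,3,AR
P45,IV,TRUE,FALSE,FALSE,TRUE,C1,3,AR
P46,IV,TRUE,FALSE,FALSE,TRUE,C1,3,AR
P47,IV,TRUE,TRUE,TRUE,TRUE,C1,3,AR
P48,IV,TRUE,TRUE,TRUE,TRUE,C1,3,AR
P49,IV,TRUE,TRUE,TRUE,TRUE,C1,3,AR
P50,IV,TRUE,TRUE,FALSE,TRUE,C2,3,AR
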