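start,end,chapter
A00,B99,infectious
C00,D48,neoplasms
D50,D89,blood
E00,E90,endocrine
F00,F99,mental
G00,G99,nervous
H00,H59,eye
H60,H95,ear
I00,I99,circulatory
J00,J99,respiratory
K00,K93,digestive
L00,L99,skin
M00,M99,musculoskeletal
N00,N99,genitourinary
O00,O99,pregnancy
P00,P96,perinatal
Q00,Q99,congenital
R00,R99,symptoms
S00,T98,injury
V01,Y98,external
Z00,Z99,factors
U00,U99,special
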