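start,end,label,profile_eligible
A00,B99,Certain infectious and parasitic diseases,TRUE
C00,D48,Neoplasms,TRUE
D50,D89,Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism,TRUE
E00,E90,Endocrine nutritional and metabolic diseases,TRUE
F00,F99,Mental and behavioural disorders,TRUE
G00,G99,Diseases of the nervous system,TRUE
H00,H59,Diseases of the eye and adnexa,TRUE
H60,H95,Diseases of the ear and mastoid process,TRUE
I00,I99,Diseases of the circulatory system,TRUE
J00,J99,Diseases of the respiratory system,TRUE
K00,K93,Diseases of the digestive system,TRUE
L00,L99,Diseases of the skin and subcutaneous tissue,TRUE
M00,M99,Diseases of the musculoskeletal system and connective tissue,TRUE
N00,N99,Diseases of the genitourinary system,TRUE
O00,O99,Pregnancy childbirth and the puerperium,TRUE
P00,P96,Certain conditions originating in the perinatal period,TRUE
Q00,Q99,Congenital malformations deformations and chromosomal abnormalities,TRUE
R00,R99,Symptoms signs and abnormal clinical and laboratory findings not elsewhere classified,TRUE
S00,T98,Injury poisoning and certain other consequences of external causes,TRUE
U00,U99,Codes for special purposes,TRUE
V01,Y98,External causes of morbidity and mortality,TRUE
Z00,Z99,Factors influencing health status and contact with health services,FALSE
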