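Code,Drug_Name,Generic,Drug_Class
1,Benazepril,,ACE
2,Lotensin,benazepril,ACE
3,Captopril,,ACE
4,Capoten,captopril,ACE
5,Enalapril,,ACE
6,Enalaprilat,enalapril,ACE
7,Fosinopril,,ACE
8,Monopril,fosinopril,ACE
9,Lisinopril,,ACE
10,Prinivil,lisinopril,ACE
11,Zestril,lisinopril,ACE
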