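RxCUI,Drug_Product,Rx_Norm_Drug_Class
858926,Enalapril Maleate 20 MG Chewable Tablet,ACE
378269,Enalapril Chewable Tablet,ACE
858810,Enalapril Maleate 20 MG Oral Tablet,ACE
858804,Enalapril Maleate 2.5 MG Oral Tablet,ACE
858821,Enalapril Maleate 1.25 MG/ML Injectable Solution,ACE
858817,Enalapril Maleate 10 MG Oral Tablet,ACE
858813,Enalapril Maleate 5 MG Oral Tablet,ACE
372007,Enalapril Oral Tablet,ACE
378288,Enalapril Injectable Solution,ACE
246264,Enalaprilat 1 MG/ML Injectable Solution,ACE
374378,Enalaprilat Injectable Solution,ACE
252820,Enalaprilat 0.625 MG/ML Injectable Solution,ACE
204404,Enalaprilat 1.25 MG/ML Injectable Solution,ACE
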