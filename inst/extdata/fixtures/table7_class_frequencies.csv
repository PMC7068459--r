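class_label,count,percent
ACE,443835,21.24
BETA_BLOCKER,411721,19.70
CCB,360653,17.26
THIAZIDE,217474,10.41
ARB,178252,8.53
LOOP_DIURETIC,115931,5.55
THIAZIDE+ACE,92275,4.42
THIAZIDE+ARB,63010,3.02
CENTRAL_ACTING,56501,2.70
VASODILATOR,30665,1.47
ALDOSTERONE_ANTAGONIST,29214,1.40
ALPHA1_BLOCKER,26995,1.29
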