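region,anatomical_group
AC,mPFC
PL,mPFC
IL,mPFC
BLA,amygdala
BMA,amygdala
CEA,amygdala
LA,amygdala
MEA,amygdala
dCA1,hippocampus
dDG,hippocampus
vCA1,hippocampus
vDG,hippocampus
vSUB,PH
PER_35,PH
PER_36,PH
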