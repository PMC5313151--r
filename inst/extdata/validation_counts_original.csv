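species,plots_reported,n_pp,n_pa,n_ap,n_aa,agreement_reported,kappa_reported,class_reported
Balsam fir,281,64,12,62,143,73.6,0.45,moderate
Black spruce,158,14,4,38,102,73.4,0.29,fair
Eastern larch,76,21,0,36,19,52.6,0.23,fair
Aspen,48,1,0,36,11,25.0,0.01,poor
Red pine,13,1,0,2,10,84.6,0.45,moderate
Red spruce,304,63,42,15,184,81.3,0.56,moderate
White spruce,72,6,2,48,16,30.6,0,poor
White pine,162,42,6,66,48,55.5,0.22,fair
White birch,25,1,1,10,13,56.0,0.02,poor
Yellow birch,53,16,1,21,15,59.5,0.3,fair
Hemlock,47,0,1,1,45,95.5,0.02,poor
Red maple,85,13,4,20,48,71.8,0.34,fair
Red oak,58,0,1,29,28,42.3,0,poor
Sugar maple,27,5,0,4,18,85.2,0.63,good
White ash,136,3,3,48,82,61.4,0.03,poor
Beech,33,8,0,7,18,78.9,0.55,moderate
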