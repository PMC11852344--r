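group,n,wss_aorta,wss_aorta_sd,ke_aorta,ke_aorta_sd,vpeak_lvot,vpeak_lvot_sd,ke_lvot,ke_lvot_sd,av_forward,av_forward_sd,mv_forward,mv_forward_sd,strain_lvot,strain_lvot_sd
isolated_myectomy,3,0.73,0.1,480.8,68,1.63,0.3,314.2,62,63,6,84,19,-10.4,3.7
myectomy_amvle,3,0.59,0.04,359.9,51,1.53,0.02,350.2,106,90,9,74,12,-12.8,1.7
healthy_control,3,0.47,0.01,345.4,33,1.25,0,345.4,33,86,21,83,13,-15.1,2.5
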