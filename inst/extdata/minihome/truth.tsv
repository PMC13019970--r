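sample_id	w_soil	w_human	w_outdoor	w_home
home_1.entrance_IBZ.wm02	0	0.5	0.3	0.2
home_1.entrance_IBZ.wp00	0	0.5	0.3	0.2
home_1.entrance_IBZ.wp02	0.0999947181954867	0.450002640902257	0.270001584541354	0.180001056360903
home_1.entrance_IBZ.wp04	0.049994718334974	0.475002640832513	0.285001584499508	0.190001056333005
home_1.entrance_IBZ.wp06	0.0999947181954867	0.450002640902257	0.270001584541354	0.180001056360903
home_1.entrance_ABZ.wm02	0	0.5	0.3	0.2
home_1.entrance_ABZ.wp00	0	0.5	0.3	0.2
home_1.entrance_ABZ.wp02	0.0799957745563894	0.460002112721805	0.276001267633083	0.184000845088722
home_1.entrance_ABZ.wp04	0.0399957746679792	0.48000211266601	0.288001267599606	0.192000845066404
home_1.entrance_ABZ.wp06	0.0799957745563894	0.460002112721805	0.276001267633083	0.184000845088722
home_1.LR_IBZ.wm02	0	0.5	0.3	0.2
home_1.LR_IBZ.wp00	0	0.5	0.3	0.2
home_1.LR_IBZ.wp02	0.0499973590977434	0.475001320451128	0.285000792270677	0.190000528180451
home_1.LR_IBZ.wp04	0.024997359167487	0.487501320416256	0.292500792249754	0.195000528166503
home_1.LR_IBZ.wp06	0.0499973590977434	0.475001320451128	0.285000792270677	0.190000528180451
home_1.LR_ABZ.wm02	0	0.5	0.3	0.2
home_1.LR_ABZ.wp00	0	0.5	0.3	0.2
home_1.LR_ABZ.wp02	0.0399978872781947	0.480001056360903	0.288000633816542	0.192000422544361
home_1.LR_ABZ.wp04	0.0199978873339896	0.490001056333005	0.294000633799803	0.196000422533202
home_1.LR_ABZ.wp06	0.0399978872781947	0.480001056360903	0.288000633816542	0.192000422544361
control_1.entrance_IBZ.wm02	0	0.5	0.3	0.2
control_1.entrance_IBZ.wp00	0	0.5	0.3	0.2
control_1.entrance_IBZ.wp02	0	0.5	0.3	0.2
control_1.entrance_IBZ.wp04	0	0.5	0.3	0.2
control_1.entrance_IBZ.wp06	0	0.5	0.3	0.2
control_1.entrance_ABZ.wm02	0	0.5	0.3	0.2
control_1.entrance_ABZ.wp00	0	0.5	0.3	0.2
control_1.entrance_ABZ.wp02	0	0.5	0.3	0.2
control_1.entrance_ABZ.wp04	0	0.5	0.3	0.2
control_1.entrance_ABZ.wp06	0	0.5	0.3	0.2
control_1.LR_IBZ.wm02	0	0.5	0.3	0.2
control_1.LR_IBZ.wp00	0	0.5	0.3	0.2
control_1.LR_IBZ.wp02	0	0.5	0.3	0.2
control_1.LR_IBZ.wp04	0	0.5	0.3	0.2
control_1.LR_IBZ.wp06	0	0.5	0.3	0.2
control_1.LR_ABZ.wm02	0	0.5	0.3	0.2
control_1.LR_ABZ.wp00	0	0.5	0.3	0.2
control_1.LR_ABZ.wp02	0	0.5	0.3	0.2
control_1.LR_ABZ.wp04	0	0.5	0.3	0.2
control_1.LR_ABZ.wp06	0	0.5	0.3	0.2
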