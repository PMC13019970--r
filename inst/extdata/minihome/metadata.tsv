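sample_id	home	sample_type	location	height	week	is_control_home	kingdom
home_1.entrance_IBZ.wm02	home_1	settled_dust	entrance	IBZ	-2	FALSE	bacteria
home_1.entrance_IBZ.wp00	home_1	settled_dust	entrance	IBZ	0	FALSE	bacteria
home_1.entrance_IBZ.wp02	home_1	settled_dust	entrance	IBZ	2	FALSE	bacteria
home_1.entrance_IBZ.wp04	home_1	settled_dust	entrance	IBZ	4	FALSE	bacteria
home_1.entrance_IBZ.wp06	home_1	settled_dust	entrance	IBZ	6	FALSE	bacteria
home_1.entrance_ABZ.wm02	home_1	settled_dust	entrance	ABZ	-2	FALSE	bacteria
home_1.entrance_ABZ.wp00	home_1	settled_dust	entrance	ABZ	0	FALSE	bacteria
home_1.entrance_ABZ.wp02	home_1	settled_dust	entrance	ABZ	2	FALSE	bacteria
home_1.entrance_ABZ.wp04	home_1	settled_dust	entrance	ABZ	4	FALSE	bacteria
home_1.entrance_ABZ.wp06	home_1	settled_dust	entrance	ABZ	6	FALSE	bacteria
home_1.LR_IBZ.wm02	home_1	settled_dust	living_room	IBZ	-2	FALSE	bacteria
home_1.LR_IBZ.wp00	home_1	settled_dust	living_room	IBZ	0	FALSE	bacteria
home_1.LR_IBZ.wp02	home_1	settled_dust	living_room	IBZ	2	FALSE	bacteria
home_1.LR_IBZ.wp04	home_1	settled_dust	living_room	IBZ	4	FALSE	bacteria
home_1.LR_IBZ.wp06	home_1	settled_dust	living_room	IBZ	6	FALSE	bacteria
home_1.LR_ABZ.wm02	home_1	settled_dust	living_room	ABZ	-2	FALSE	bacteria
home_1.LR_ABZ.wp00	home_1	settled_dust	living_room	ABZ	0	FALSE	bacteria
home_1.LR_ABZ.wp02	home_1	settled_dust	living_room	ABZ	2	FALSE	bacteria
home_1.LR_ABZ.wp04	home_1	settled_dust	living_room	ABZ	4	FALSE	bacteria
home_1.LR_ABZ.wp06	home_1	settled_dust	living_room	ABZ	6	FALSE	bacteria
control_1.entrance_IBZ.wm02	control_1	settled_dust	entrance	IBZ	-2	TRUE	bacteria
control_1.entrance_IBZ.wp00	control_1	settled_dust	entrance	IBZ	0	TRUE	bacteria
control_1.entrance_IBZ.wp02	control_1	settled_dust	entrance	IBZ	2	TRUE	bacteria
control_1.entrance_IBZ.wp04	control_1	settled_dust	entrance	IBZ	4	TRUE	bacteria
control_1.entrance_IBZ.wp06	control_1	settled_dust	entrance	IBZ	6	TRUE	bacteria
control_1.entrance_ABZ.wm02	control_1	settled_dust	entrance	ABZ	-2	TRUE	bacteria
control_1.entrance_ABZ.wp00	control_1	settled_dust	entrance	ABZ	0	TRUE	bacteria
control_1.entrance_ABZ.wp02	control_1	settled_dust	entrance	ABZ	2	TRUE	bacteria
control_1.entrance_ABZ.wp04	control_1	settled_dust	entrance	ABZ	4	TRUE	bacteria
control_1.entrance_ABZ.wp06	control_1	settled_dust	entrance	ABZ	6	TRUE	bacteria
control_1.LR_IBZ.wm02	control_1	settled_dust	living_room	IBZ	-2	TRUE	bacteria
control_1.LR_IBZ.wp00	control_1	settled_dust	living_room	IBZ	0	TRUE	bacteria
control_1.LR_IBZ.wp02	control_1	settled_dust	living_room	IBZ	2	TRUE	bacteria
control_1.LR_IBZ.wp04	control_1	settled_dust	living_room	IBZ	4	TRUE	bacteria
control_1.LR_IBZ.wp06	control_1	settled_dust	living_room	IBZ	6	TRUE	bacteria
control_1.LR_ABZ.wm02	control_1	settled_dust	living_room	ABZ	-2	TRUE	bacteria
control_1.LR_ABZ.wp00	control_1	settled_dust	living_room	ABZ	0	TRUE	bacteria
control_1.LR_ABZ.wp02	control_1	settled_dust	living_room	ABZ	2	TRUE	bacteria
control_1.LR_ABZ.wp04	control_1	settled_dust	living_room	ABZ	4	TRUE	bacteria
control_1.LR_ABZ.wp06	control_1	settled_dust	living_room	ABZ	6	TRUE	bacteria
home_1.soil.wp00.r1	home_1	source_aliquot	source	none	0	FALSE	bacteria
home_1.soil.wp00.r2	home_1	source_aliquot	source	none	0	FALSE	bacteria
home_1.soil.wp04.r1	home_1	source_aliquot	source	none	4	FALSE	bacteria
home_1.soil.wp04.r2	home_1	source_aliquot	source	none	4	FALSE	bacteria
blank.01	lab	control_blank	none	none	NA	FALSE	bacteria
blank.02	lab	control_blank	none	none	NA	FALSE	bacteria
blank.03	lab	control_blank	none	none	NA	FALSE	bacteria
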