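strategy	gene	ko
potassium_uptake	trkH	K03498
potassium_uptake	trkA	K03499
sodium_solute_symport	sss	NA
compatible_solute_uptake	opuA	NA
compatible_solute_uptake	opuC	NA
compatible_solute_uptake	opuD	NA
compatible_solute_uptake	opuBD	NA
compatible_solute_uptake	betT	NA
glycerol_utilization	glpK	NA
glycerol_utilization	glpA	NA
glycerol_utilization	glpB	NA
glycerol_utilization	glpC	NA
trehalose_biosynthesis	glgA	NA
trehalose_biosynthesis	glgC	NA
trehalose_biosynthesis	treX	NA
ectoine_biosynthesis	asd	NA
ectoine_biosynthesis	ectB	NA
ectoine_biosynthesis	lysC	NA
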