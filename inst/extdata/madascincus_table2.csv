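quantity,method_a,method_b,printed,consistent,figure_derived
ctax,BAT,MTMC,0.80,TRUE,FALSE
ctax,HW,MTMC,0.43,FALSE,TRUE
ctax,HW,BAT,0.57,FALSE,TRUE
ctax,BSD,MTMC,0.42,TRUE,FALSE
ctax,BSD,BAT,0.53,TRUE,FALSE
ctax,BSD,HW,0.63,FALSE,TRUE
ctax,GMYC,MTMC,0.24,TRUE,FALSE
ctax,GMYC,BAT,0.30,TRUE,FALSE
ctax,GMYC,HW,0.36,TRUE,TRUE
ctax,GMYC,BSD,0.57,FALSE,FALSE
ctax,ITAX,MTMC,0.72,FALSE,FALSE
ctax,ITAX,BAT,0.91,TRUE,FALSE
ctax,ITAX,HW,0.64,FALSE,TRUE
ctax,ITAX,BSD,0.57,FALSE,FALSE
ctax,ITAX,GMYC,0.33,TRUE,FALSE
ctax,WP,MTMC,0.67,TRUE,FALSE
ctax,WP,BAT,0.57,TRUE,FALSE
ctax,WP,HW,0.33,FALSE,TRUE
ctax,WP,BSD,0.63,TRUE,FALSE
ctax,WP,GMYC,0.36,TRUE,FALSE
ctax,WP,ITAX,0.53,TRUE,FALSE
mean_ctax,MTMC,,0.52,FALSE,FALSE
rtax,MTMC,,0.24,TRUE,FALSE
n_species,MTMC,,9,TRUE,FALSE
mean_ctax,BAT,,0.61,FALSE,FALSE
rtax,BAT,,0.30,TRUE,FALSE
n_species,BAT,,11,TRUE,FALSE
mean_ctax,HW,,0.49,FALSE,TRUE
rtax,HW,,0.36,TRUE,TRUE
n_species,HW,,13,TRUE,TRUE
mean_ctax,BSD,,0.56,FALSE,FALSE
rtax,BSD,,0.57,FALSE,FALSE
n_species,BSD,,20,TRUE,FALSE
mean_ctax,GMYC,,0.35,FALSE,FALSE
rtax,GMYC,,1.00,TRUE,FALSE
n_species,GMYC,,34,TRUE,FALSE
mean_ctax,ITAX,,0.62,FALSE,FALSE
rtax,ITAX,,0.33,TRUE,FALSE
n_species,ITAX,,12,TRUE,FALSE
mean_ctax,WP,,0.51,FALSE,FALSE
rtax,WP,,0.36,TRUE,FALSE
n_species,WP,,13,TRUE,FALSE
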