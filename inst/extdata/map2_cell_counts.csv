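experiment,clone,genotype,n_map2_cells,reported_total
GluN1,wt_4,wildtype,4681,54654
GluN1,wt_61,wildtype,11445,54654
GluN1,het_10.23,het,5323,54654
GluN1,het_42.13,het,7323,54654
GluN1,hom_20,hom,6833,54654
GluN1,hom_44,hom,19049,54654
VGLUT1,wt_4,wildtype,4241,45371
VGLUT1,wt_61,wildtype,10302,45371
VGLUT1,het_10.23,het,5257,45371
VGLUT1,het_42.13,het,5580,45371
VGLUT1,hom_20,hom,5550,45371
VGLUT1,hom_44,hom,14441,45371
RPS6,wt_4,wildtype,6712,55150
RPS6,wt_61,wildtype,13241,55150
RPS6,het_10.23,het,8984,55150
RPS6,het_42.13,het,4838,55150
RPS6,hom_20,hom,7772,55150
RPS6,hom_44,hom,13603,55150
SUnSET,wt_4,wildtype,8539,35461
SUnSET,wt_61,wildtype,5313,35461
SUnSET,het_10.23,het,7268,35461
SUnSET,het_42.13,het,5487,35461
SUnSET,hom_20,hom,4970,35461
SUnSET,hom_44,hom,3353,35461
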