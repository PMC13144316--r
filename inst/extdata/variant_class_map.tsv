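maf_term	classification
Missense_Mutation	missense
Nonsense_Mutation	nonsense
Frame_Shift_Ins	frameshift_ins
Frame_Shift_Del	frameshift_del
In_Frame_Ins	inframe_ins
In_Frame_Del	inframe_del
Splice_Site	splice_site
Translation_Start_Site	translation_start_site
Silent	silent
3'UTR	utr3
5'UTR	utr5
Intron	intron
3'Flank	flank
5'Flank	flank
Splice_Region	other
Nonstop_Mutation	other
IGR	other
RNA	other
Targeted_Region	other
missense	missense
nonsense	nonsense
frameshift_ins	frameshift_ins
frameshift_del	frameshift_del
inframe_ins	inframe_ins
inframe_del	inframe_del
splice_site	splice_site
translation_start_site	translation_start_site
silent	silent
utr3	utr3
utr5	utr5
intron	intron
flank	flank
other	other
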