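gene	inheritance_model	family	hgvs_c	hgvs_p	change	consequence	provean	sift	polyphen	ac_inhouse	an_inhouse	ac_1kg	an_1kg	ac_exac	an_exac	ac_exac_eas	an_exac_eas
PRPF4	sporadic	RP-145	c.1541C > T	p.Thr514Ile	heterozygous	Nonsynonymous	Deleterious	Damaging	Probably damaging	2	4040	0	5008	0	121412	0	8640
RDH12	sporadic	RP-050	c.940C > T	p.Arg314Trp	heterozygous	Nonsynonymous	Deleterious	Damaging	Probably damaging	2	4040	0	5008	2	121412	0	8612
RDH12	sporadic	RP-060	c.437T > A	p.Val146Asp	heterozygous	Nonsynonymous	Deleterious	Damaging	Probably damaging	2	4040	0	5008	0	121412	0	8612
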