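# 19-SNP coronary artery disease genetic risk score locus table.
# The locus list and proxy relationships are real; the alleles and the
# numeric log odds ratio weights below are SYNTHETIC PLACEHOLDERS of
# realistic magnitude -- the published CARDIoGRAM effect sizes are not
# reproduced here. Replace this table for any substantive use.
rsid	effect_allele	other_allele	weight	proxy_for
rs17465637	C	A	0.12
rs9970807	C	T	0.17	rs17114036
rs6725887	C	T	0.14
rs2306374	C	T	0.08
rs12190287	C	T	0.10
rs12204265	A	G	0.09	rs17609940
rs12526453	C	T	0.11
rs11556924	C	T	0.10
rs4977574	G	A	0.21
rs1746048	C	T	0.09
rs2246833	T	C	0.07
rs2505083	C	T	0.06
rs974819	T	C	0.08
rs4773144	G	A	0.07
rs2895811	C	T	0.06
rs7177699	T	C	0.08	rs3825807
rs12449964	T	C	0.07	rs12936587
rs143499	G	A	0.06	rs216172
rs9305545	A	G	0.13	rs9982601
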