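enzyme	pathway	man_fold	man_code	man_pbin	gal_fold	gal_code	gal_pbin	pyr_fold	pyr_code	pyr_pbin
Yea6p	tca	NA	nsc		NA	nsc		NA	nsc
Pda1p	tca	NA	nsc		NA	nsc		2.8	ok
Pdb1p	tca	NA	nsc		3.0	ok		2.7	ok
Lat1p	tca	NA	nsc		NA	nsc		NA	nsc
Lpd1p	tca	NA	nsc		3.1	ok		5.1	ok	*
Pdx1p	tca	NA	nsc		NA	nsc		0	bd
Cit1p	tca	NA	nsc		6.0	ok		14.1	ok
Cit3p	tca	NA	nsc		NA	nsc		NA	nsc
Aco2p	tca	NA	nsc		NA	nsc		0.3	ok
Idh1p	tca	NA	nsc		2.1	ok		3.0	ok
Idh2p	tca	NA	nsc		2.5	ok		3.6	ok
Idp1p	tca	NA	nsc		NA	nsc		0.6	ok
Kgd1p	tca	NA	nsc		2.7	ok		2.9	ok
Kgd2p	tca	NA	nsc		NA	nsc		NA	nsc
Lsc1p	tca	NA	nsc		NA	nsc		2.5	ok
Lsc2p	tca	NA	nsc		NA	nsc		NA	nsc
Sdh2p	tca	0	bd		4.8	ok		4.6	ok	**
Sdh4p	tca	NA	nsc		NA	nsc		2.8	ok	*
Fum1p	tca	NA	nsc		3.1	ok		6.8	ok
Mdh1p	tca	NA	nsc		3.9	ok		7.4	ok	*
Mae1p	tca	NA	nsc		0.4	ok	**	0	bd
Ndi1p	respiratory_chain	NA	nsc		2.4	ok		2.1	ok	*
Nde1p	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Cyt1p	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Cor1p	respiratory_chain	NA	nsc		3.8	ok		6.0	ok
Qcr2p	respiratory_chain	NA	nsc		NA	nsc		5.9	ok
Qcr6p	respiratory_chain	NA	nsc		3.7	ok		2.8	ok	*
Qcr7p	respiratory_chain	NA	nsc		2.5	ok		NA	nsc
Qcr8p	respiratory_chain	0.2	ok	*	NA	nsc		0.2	ok
Qcr9p	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Qcr10p	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Rip1p	respiratory_chain	NA	nsc		NA	ng		NA	ng
Cox4p	respiratory_chain	NA	nsc		3.6	ok	*	5.1	ok
Cox5ap	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Cox5bp	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Cox6p	respiratory_chain	NA	nsc		3.9	ok		5.8	ok	*
Cox7p	respiratory_chain	NA	nsc		5.0	ok		NA	nsc
Cox8p	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Cox9p	respiratory_chain	NA	nsc		NA	nsc		NA	nsc
Cox12p	respiratory_chain	NA	nsc		NA	ng		NA	ng
Pdc1p	ethanol	0.9	ok		0.6	ok		0.4	ok
Pdc5p	ethanol	NA	nsc		NA	nsc		NA	nsc
Pdc6p	ethanol	NA	nsc		NA	nsc		NA	nsc
Adh2p	ethanol	NA	nsc		NA	nsc		16.9	ok
Adh4p	ethanol	0	bd	*	0.1	ok	*	0.2	ok	*
Adh5p	ethanol	NA	nsc		0.1	ok		0.1	ok
Sfa1p	ethanol	NA	nsc		NA	nsc		NA	nsc
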