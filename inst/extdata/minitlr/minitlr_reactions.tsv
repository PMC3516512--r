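id	formula	lb	ub	gpr	rclass
EX_lpsA	lpsA[e] <=>	-1000	1000		exchange
EX_rnaB	rnaB[e] <=>	-1000	1000		exchange
EX_dnaC	dnaC[e] <=>	-1000	1000		exchange
EX_atp	atp[c] <=>	-1000	1000		exchange
EX_adp	adp[c] <=>	-1000	1000		exchange
EX_gtp	gtp[c] <=>	-1000	1000		exchange
EX_gdp	gdp[c] <=>	-1000	1000		exchange
BIND_A	lpsA[e] -> sigA[c]	0	1000	101	binding
BIND_B	rnaB[e] -> sigB[c]	0	1000	102	binding
BIND_C	dnaC[e] -> sigC[c]	0	1000	103	binding
BIND_O1	orphan1[e] -> sigA[c]	0	1000	104	binding
BIND_O2	orphan2[e] -> sigB[c]	0	1000	105	binding
SK_sigA	sigA[c] ->	0	1000		sink
SK_sigB	sigB[c] ->	0	1000		sink
SK_sigC	sigC[c] ->	0	1000		sink
ADAPT_A	atp[c] + sigA[c] -> adap[c] + adp[c]	0	1000	201 or 202	core
ADAPT_B	atp[c] + sigB[c] -> adap[c] + adp[c]	0	1000	201 or 202	core
ADAPT_C	atp[c] + sigC[c] -> adap[c] + adp[c]	0	1000	201 or 202	core
KIN1	adap[c] + atp[c] -> adp[c] + kin1[c]	0	1000	301 or 302 or 303	core
KIN2	atp[c] + kin1[c] -> adp[c] + kin2[c]	0	1000	401 and 402	core
TF_NFKB	kin2[c] -> tfNFKB[c]	0	1000	501	core
TF_AP1	2 kin2[c] -> tfAP1[c]	0	1000	502 and 503	core
TF_CREB	kin2[c] -> tfCREB[c]	0	1000	504	core
TF_IRF	atp[c] + sigA[c] + sigB[c] -> adp[c] + tfIRF[c]	0	1000	505	core
ROS_SYN	gtp[c] + kin1[c] -> gdp[c] + ros[v]	0	1000	601 and 602	core
NFKB_TRANS	tfNFKB[c] -> nfkb[n]	0	1000		transport
AP1_TRANS	tfAP1[c] -> ap1[n]	0	1000		transport
CREB_BIND	tfCREB[c] -> creb[n]	0	1000		transport
CREB_EXPORT	creb[n] -> tfCREB[c]	0	1000		transport
IRF_TRANS	tfIRF[c] -> irf[n]	0	1000		transport
DM_nfkb	nfkb[n] ->	0	1000		demand
DM_ap1	ap1[n] ->	0	1000		demand
DM_creb	creb[n] ->	0	1000		demand
DM_irf	irf[n] ->	0	1000		demand
DM_ros	ros[v] ->	0	1000		demand
LOOP_F	loopx[c] -> loopy[c]	0	1000	701	core
LOOP_R	loopy[c] -> loopx[c]	0	1000		core
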