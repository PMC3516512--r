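section	scenario	id	key	value
fva	baseline	DM_nfkb	min	0
fva	baseline	DM_nfkb	max	-0
fva	baseline	DM_ap1	min	0
fva	baseline	DM_ap1	max	-0
fva	baseline	DM_creb	min	0
fva	baseline	DM_creb	max	-0
fva	baseline	CREB_BIND	min	0
fva	baseline	CREB_BIND	max	1000
fva	baseline	DM_irf	min	0
fva	baseline	DM_irf	max	-0
fva	baseline	DM_ros	min	0
fva	baseline	DM_ros	max	-0
fva	RA	DM_nfkb	min	0
fva	RA	DM_nfkb	max	1
fva	RA	DM_ap1	min	0
fva	RA	DM_ap1	max	0.5
fva	RA	DM_creb	min	0
fva	RA	DM_creb	max	1
fva	RA	CREB_BIND	min	0
fva	RA	CREB_BIND	max	1000
fva	RA	DM_irf	min	0
fva	RA	DM_irf	max	-0
fva	RA	DM_ros	min	0
fva	RA	DM_ros	max	1
fva	RB	DM_nfkb	min	0
fva	RB	DM_nfkb	max	1
fva	RB	DM_ap1	min	0
fva	RB	DM_ap1	max	0.5
fva	RB	DM_creb	min	0
fva	RB	DM_creb	max	1
fva	RB	CREB_BIND	min	0
fva	RB	CREB_BIND	max	1000
fva	RB	DM_irf	min	0
fva	RB	DM_irf	max	-0
fva	RB	DM_ros	min	0
fva	RB	DM_ros	max	1
fva	RC	DM_nfkb	min	0
fva	RC	DM_nfkb	max	1
fva	RC	DM_ap1	min	0
fva	RC	DM_ap1	max	0.5
fva	RC	DM_creb	min	0
fva	RC	DM_creb	max	1
fva	RC	CREB_BIND	min	0
fva	RC	CREB_BIND	max	1000
fva	RC	DM_irf	min	0
fva	RC	DM_irf	max	-0
fva	RC	DM_ros	min	0
fva	RC	DM_ros	max	1
fva	RA+RB	DM_nfkb	min	0
fva	RA+RB	DM_nfkb	max	2
fva	RA+RB	DM_ap1	min	0
fva	RA+RB	DM_ap1	max	1
fva	RA+RB	DM_creb	min	0
fva	RA+RB	DM_creb	max	2
fva	RA+RB	CREB_BIND	min	0
fva	RA+RB	CREB_BIND	max	1000
fva	RA+RB	DM_irf	min	0
fva	RA+RB	DM_irf	max	1
fva	RA+RB	DM_ros	min	0
fva	RA+RB	DM_ros	max	2
blocked	shipped	BIND_O1	blocked	1
blocked	shipped	BIND_O2	blocked	1
dead_end	shipped	orphan1[e]	dead_end	1
dead_end	shipped	orphan2[e]	dead_end	1
subnet	ap1_complex	n_reactions	count	1
subnet	ap1_complex	n_compounds	count	2
subnet	up_set	n_reactions	count	5
subnet	up_set	n_compounds	count	9
curve	RA_DM_nfkb_atp	00	-25	1
curve	RA_DM_nfkb_atp	01	-24.48979592	1
curve	RA_DM_nfkb_atp	02	-23.97959184	1
curve	RA_DM_nfkb_atp	03	-23.46938776	1
curve	RA_DM_nfkb_atp	04	-22.95918367	1
curve	RA_DM_nfkb_atp	05	-22.44897959	1
curve	RA_DM_nfkb_atp	06	-21.93877551	1
curve	RA_DM_nfkb_atp	07	-21.42857143	1
curve	RA_DM_nfkb_atp	08	-20.91836735	1
curve	RA_DM_nfkb_atp	09	-20.40816327	1
curve	RA_DM_nfkb_atp	10	-19.89795918	1
curve	RA_DM_nfkb_atp	11	-19.3877551	1
curve	RA_DM_nfkb_atp	12	-18.87755102	1
curve	RA_DM_nfkb_atp	13	-18.36734694	1
curve	RA_DM_nfkb_atp	14	-17.85714286	1
curve	RA_DM_nfkb_atp	15	-17.34693878	1
curve	RA_DM_nfkb_atp	16	-16.83673469	1
curve	RA_DM_nfkb_atp	17	-16.32653061	1
curve	RA_DM_nfkb_atp	18	-15.81632653	1
curve	RA_DM_nfkb_atp	19	-15.30612245	1
curve	RA_DM_nfkb_atp	20	-14.79591837	1
curve	RA_DM_nfkb_atp	21	-14.28571429	1
curve	RA_DM_nfkb_atp	22	-13.7755102	1
curve	RA_DM_nfkb_atp	23	-13.26530612	1
curve	RA_DM_nfkb_atp	24	-12.75510204	1
curve	RA_DM_nfkb_atp	25	-12.24489796	1
curve	RA_DM_nfkb_atp	26	-11.73469388	1
curve	RA_DM_nfkb_atp	27	-11.2244898	1
curve	RA_DM_nfkb_atp	28	-10.71428571	1
curve	RA_DM_nfkb_atp	29	-10.20408163	1
curve	RA_DM_nfkb_atp	30	-9.693877551	1
curve	RA_DM_nfkb_atp	31	-9.183673469	1
curve	RA_DM_nfkb_atp	32	-8.673469388	1
curve	RA_DM_nfkb_atp	33	-8.163265306	1
curve	RA_DM_nfkb_atp	34	-7.653061224	1
curve	RA_DM_nfkb_atp	35	-7.142857143	1
curve	RA_DM_nfkb_atp	36	-6.632653061	1
curve	RA_DM_nfkb_atp	37	-6.12244898	1
curve	RA_DM_nfkb_atp	38	-5.612244898	1
curve	RA_DM_nfkb_atp	39	-5.102040816	1
curve	RA_DM_nfkb_atp	40	-4.591836735	1
curve	RA_DM_nfkb_atp	41	-4.081632653	1
curve	RA_DM_nfkb_atp	42	-3.571428571	1
curve	RA_DM_nfkb_atp	43	-3.06122449	1
curve	RA_DM_nfkb_atp	44	-2.551020408	0.8503401361
curve	RA_DM_nfkb_atp	45	-2.040816327	0.6802721088
curve	RA_DM_nfkb_atp	46	-1.530612245	0.5102040816
curve	RA_DM_nfkb_atp	47	-1.020408163	0.3401360544
curve	RA_DM_nfkb_atp	48	-0.5102040816	0.1700680272
curve	RA_DM_nfkb_atp	49	0	-0
curve	RA_DM_nfkb_gtp	00	-25	1
curve	RA_DM_nfkb_gtp	01	-24.48979592	1
curve	RA_DM_nfkb_gtp	02	-23.97959184	1
curve	RA_DM_nfkb_gtp	03	-23.46938776	1
curve	RA_DM_nfkb_gtp	04	-22.95918367	1
curve	RA_DM_nfkb_gtp	05	-22.44897959	1
curve	RA_DM_nfkb_gtp	06	-21.93877551	1
curve	RA_DM_nfkb_gtp	07	-21.42857143	1
curve	RA_DM_nfkb_gtp	08	-20.91836735	1
curve	RA_DM_nfkb_gtp	09	-20.40816327	1
curve	RA_DM_nfkb_gtp	10	-19.89795918	1
curve	RA_DM_nfkb_gtp	11	-19.3877551	1
curve	RA_DM_nfkb_gtp	12	-18.87755102	1
curve	RA_DM_nfkb_gtp	13	-18.36734694	1
curve	RA_DM_nfkb_gtp	14	-17.85714286	1
curve	RA_DM_nfkb_gtp	15	-17.34693878	1
curve	RA_DM_nfkb_gtp	16	-16.83673469	1
curve	RA_DM_nfkb_gtp	17	-16.32653061	1
curve	RA_DM_nfkb_gtp	18	-15.81632653	1
curve	RA_DM_nfkb_gtp	19	-15.30612245	1
curve	RA_DM_nfkb_gtp	20	-14.79591837	1
curve	RA_DM_nfkb_gtp	21	-14.28571429	1
curve	RA_DM_nfkb_gtp	22	-13.7755102	1
curve	RA_DM_nfkb_gtp	23	-13.26530612	1
curve	RA_DM_nfkb_gtp	24	-12.75510204	1
curve	RA_DM_nfkb_gtp	25	-12.24489796	1
curve	RA_DM_nfkb_gtp	26	-11.73469388	1
curve	RA_DM_nfkb_gtp	27	-11.2244898	1
curve	RA_DM_nfkb_gtp	28	-10.71428571	1
curve	RA_DM_nfkb_gtp	29	-10.20408163	1
curve	RA_DM_nfkb_gtp	30	-9.693877551	1
curve	RA_DM_nfkb_gtp	31	-9.183673469	1
curve	RA_DM_nfkb_gtp	32	-8.673469388	1
curve	RA_DM_nfkb_gtp	33	-8.163265306	1
curve	RA_DM_nfkb_gtp	34	-7.653061224	1
curve	RA_DM_nfkb_gtp	35	-7.142857143	1
curve	RA_DM_nfkb_gtp	36	-6.632653061	1
curve	RA_DM_nfkb_gtp	37	-6.12244898	1
curve	RA_DM_nfkb_gtp	38	-5.612244898	1
curve	RA_DM_nfkb_gtp	39	-5.102040816	1
curve	RA_DM_nfkb_gtp	40	-4.591836735	1
curve	RA_DM_nfkb_gtp	41	-4.081632653	1
curve	RA_DM_nfkb_gtp	42	-3.571428571	1
curve	RA_DM_nfkb_gtp	43	-3.06122449	1
curve	RA_DM_nfkb_gtp	44	-2.551020408	1
curve	RA_DM_nfkb_gtp	45	-2.040816327	1
curve	RA_DM_nfkb_gtp	46	-1.530612245	1
curve	RA_DM_nfkb_gtp	47	-1.020408163	1
curve	RA_DM_nfkb_gtp	48	-0.5102040816	1
curve	RA_DM_nfkb_gtp	49	0	1
curve	RA_DM_ros_gtp	00	-25	1
curve	RA_DM_ros_gtp	01	-24.48979592	1
curve	RA_DM_ros_gtp	02	-23.97959184	1
curve	RA_DM_ros_gtp	03	-23.46938776	1
curve	RA_DM_ros_gtp	04	-22.95918367	1
curve	RA_DM_ros_gtp	05	-22.44897959	1
curve	RA_DM_ros_gtp	06	-21.93877551	1
curve	RA_DM_ros_gtp	07	-21.42857143	1
curve	RA_DM_ros_gtp	08	-20.91836735	1
curve	RA_DM_ros_gtp	09	-20.40816327	1
curve	RA_DM_ros_gtp	10	-19.89795918	1
curve	RA_DM_ros_gtp	11	-19.3877551	1
curve	RA_DM_ros_gtp	12	-18.87755102	1
curve	RA_DM_ros_gtp	13	-18.36734694	1
curve	RA_DM_ros_gtp	14	-17.85714286	1
curve	RA_DM_ros_gtp	15	-17.34693878	1
curve	RA_DM_ros_gtp	16	-16.83673469	1
curve	RA_DM_ros_gtp	17	-16.32653061	1
curve	RA_DM_ros_gtp	18	-15.81632653	1
curve	RA_DM_ros_gtp	19	-15.30612245	1
curve	RA_DM_ros_gtp	20	-14.79591837	1
curve	RA_DM_ros_gtp	21	-14.28571429	1
curve	RA_DM_ros_gtp	22	-13.7755102	1
curve	RA_DM_ros_gtp	23	-13.26530612	1
curve	RA_DM_ros_gtp	24	-12.75510204	1
curve	RA_DM_ros_gtp	25	-12.24489796	1
curve	RA_DM_ros_gtp	26	-11.73469388	1
curve	RA_DM_ros_gtp	27	-11.2244898	1
curve	RA_DM_ros_gtp	28	-10.71428571	1
curve	RA_DM_ros_gtp	29	-10.20408163	1
curve	RA_DM_ros_gtp	30	-9.693877551	1
curve	RA_DM_ros_gtp	31	-9.183673469	1
curve	RA_DM_ros_gtp	32	-8.673469388	1
curve	RA_DM_ros_gtp	33	-8.163265306	1
curve	RA_DM_ros_gtp	34	-7.653061224	1
curve	RA_DM_ros_gtp	35	-7.142857143	1
curve	RA_DM_ros_gtp	36	-6.632653061	1
curve	RA_DM_ros_gtp	37	-6.12244898	1
curve	RA_DM_ros_gtp	38	-5.612244898	1
curve	RA_DM_ros_gtp	39	-5.102040816	1
curve	RA_DM_ros_gtp	40	-4.591836735	1
curve	RA_DM_ros_gtp	41	-4.081632653	1
curve	RA_DM_ros_gtp	42	-3.571428571	1
curve	RA_DM_ros_gtp	43	-3.06122449	1
curve	RA_DM_ros_gtp	44	-2.551020408	1
curve	RA_DM_ros_gtp	45	-2.040816327	1
curve	RA_DM_ros_gtp	46	-1.530612245	1
curve	RA_DM_ros_gtp	47	-1.020408163	1
curve	RA_DM_ros_gtp	48	-0.5102040816	0.5102040816
curve	RA_DM_ros_gtp	49	0	-0
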