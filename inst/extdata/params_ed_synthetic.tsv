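reaction	parameter_kind	metabolite	value	sd	units	temperature_C	source
v_GDH	km	Glc	1.2	NA	mM	NA	literature
v_GAD	km	DGat	1.5	NA	mM	NA	literature
v_KDGK	km	KDG	0.8	NA	mM	NA	literature
v_KDPGA_sp	km	KDPG	0.4	NA	mM	NA	literature
v_KDPGA_np	km	KDG	2	NA	mM	NA	literature
v_KDPGA_np	km	GA	1	NA	mM	NA	literature
v_KDPGA_np	km	Pyr	5	NA	mM	NA	literature
v_GAPDH	km	GAP	0.25	NA	mM	NA	literature
v_GAPDH	km	BPG	0.06	NA	mM	NA	literature
v_GAPN	km	GAP	0.5	NA	mM	NA	literature
v_PGK	km	BPG	0.05	NA	mM	NA	literature
v_PGK	km	PG3	1	NA	mM	NA	literature
v_iPGAM	km	PG3	0.6	NA	mM	NA	literature
v_iPGAM	km	PG2	0.3	NA	mM	NA	literature
v_GAOR	km	GA	1	NA	mM	NA	literature
v_GK	km	Gly	0.5	NA	mM	NA	literature
v_ENO	km	PG2	0.4	NA	mM	NA	literature
v_ENO	km	PEP	0.5	NA	mM	NA	literature
v_PK	km	PEP	0.3	NA	mM	NA	literature
v_PEPS	km	Pyr	0.6	NA	mM	NA	literature
v_GK	ki	Gly	1	NA	mM	NA	literature
v_PGK	ki	PG3	6	NA	mM	NA	literature
	cofactor_pool	ATP	2.5	NA	mM	NA	literature
	cofactor_pool	ADP	0.8	NA	mM	NA	literature
	cofactor_pool	NADP	0.15	NA	mM	NA	literature
	cofactor_pool	NADPH	0.25	NA	mM	NA	literature
	cofactor_pool	Fd	1	NA	mM	NA	literature
	cofactor_km	ATP	0.15	NA	mM	NA	literature
	cofactor_km	ADP	0.08	NA	mM	NA	literature
	cofactor_km	NADP	0.03	NA	mM	NA	literature
	cofactor_km	NADPH	0.05	NA	mM	NA	literature
	cofactor_km	Fd	0.1	NA	mM	NA	literature
v_GDH	vmax		42.8571428571429	6.42857142857143	U/gCE	70	measured
v_GAD	vmax		44.7368421052632	6.26315789473684	U/gCE	70	measured
v_KDPGA_sp	vmax		27.2727272727273	4.09090909090909	U/gCE	70	measured
v_KDPGA_np_f	vmax		32.4324324324324	5.51351351351351	U/gCE	70	measured
v_KDPGA_np_r	vmax		12.1951219512195	2.4390243902439	U/gCE	70	measured
v_GAPDH_f	vmax		32.5581395348837	4.55813953488372	U/gCE	70	measured
v_GAPN	vmax		13.8888888888889	2.77777777777778	U/gCE	70	measured
v_PGK_f	vmax		60	9	U/gCE	70	measured
v_iPGAM_f	vmax		28.2051282051282	4.23076923076923	U/gCE	70	measured
v_PK	vmax		39.0243902439024	5.07317073170732	U/gCE	70	measured
v_PEPS	vmax		7.69230769230769	1.92307692307692	U/gCE	70	measured
v_up	vmax		10	NA	U/gCE	70	fitted
v_KDGK	vmax		13.966036745382	NA	U/gCE	70	fitted
v_GAOR	vmax		60.8183971458134	NA	U/gCE	70	fitted
v_GK	vmax		48.9825165910924	NA	U/gCE	70	fitted
v_ENO_f	vmax		22.9821342133268	NA	U/gCE	70	fitted
v_ENO_r	vmax		10.1128610706422	NA	U/gCE	70	fitted
v_GAPDH_r	vmax		34.9876673891796	NA	U/gCE	70	fitted
v_PGK_r	vmax		26.930834120055	NA	U/gCE	70	fitted
v_iPGAM_r	vmax		62.9981094723085	NA	U/gCE	70	fitted
v_sinkGAP	sink		0.527705763493221	NA	1/min	70	fitted
v_sinkPyr	sink		0.658703600972558	NA	1/min	70	fitted
v_degGAP	half_life	GAP	16	NA	min	70	measured
v_degBPG	half_life	BPG	1.9	NA	min	70	measured
v_degPEP	half_life	PEP	40	NA	min	70	measured
v_GDH	vmax		90	13.5	U/gCE	80	measured
v_GAD	vmax		85	11.9	U/gCE	80	measured
v_KDPGA_sp	vmax		60	9	U/gCE	80	measured
v_KDPGA_np_f	vmax		60	10.2	U/gCE	80	measured
v_KDPGA_np_r	vmax		25	5	U/gCE	80	measured
v_GAPDH_f	vmax		70	9.8	U/gCE	80	measured
v_GAPN	vmax		25	5	U/gCE	80	measured
v_PGK_f	vmax		120	18	U/gCE	80	measured
v_iPGAM_f	vmax		55	8.25	U/gCE	80	measured
v_PK	vmax		80	10.4	U/gCE	80	measured
v_PEPS	vmax		15	3.75	U/gCE	80	measured
v_up	vmax		19.7269327059332	NA	U/gCE	80	fitted
v_KDGK	vmax		33.5758609608841	NA	U/gCE	80	fitted
v_GAOR	vmax		94.8641183625551	NA	U/gCE	80	fitted
v_GK	vmax		90.0407232200521	NA	U/gCE	80	fitted
v_ENO_f	vmax		55.9837316314546	NA	U/gCE	80	fitted
v_ENO_r	vmax		40.564297599849	NA	U/gCE	80	fitted
v_GAPDH_r	vmax		62.4780069232344	NA	U/gCE	80	fitted
v_PGK_r	vmax		42.9082771014775	NA	U/gCE	80	fitted
v_iPGAM_r	vmax		108.601620702402	NA	U/gCE	80	fitted
v_sinkGAP	sink		0.0894614754315125	NA	1/min	80	fitted
v_sinkPyr	sink		1.35125228992395	NA	1/min	80	fitted
v_degGAP	half_life	GAP	5.8	NA	min	80	measured
v_degBPG	half_life	BPG	0.676875	NA	min	80	measured
v_degPEP	half_life	PEP	14	NA	min	80	measured
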