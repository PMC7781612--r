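subject_id	handedness	lesion_site	lesion_side	lesion_volume_cm3	stroke_type	sex	days_poststroke	age_years	fugl_meyer_total
S001	L	L pons	L	0.79	I	M	14	58	63
S002	R	R basal ganglia	R	36.47	H	F	12	57	57
S003	R	R parietal, R occipital	R	19.87	I	F	11	49	24
S004	R	R basal ganglia	R	2.54	I	F	9	65	14
S005	R	R basal ganglia	R	10.08	H	M	11	40	45
S006	A	L temporal	L	36.97	I	M	5	69	65
S007	R	R basal ganglia, R posterior corona radiata, R temporal lobe	R	15.2	I	M	16	48	13
S008	R	R temporal	R	78.1	H	M	9	50	57
S009	R	R Middle Cerebral Artery, R posterior insula, R parietal operculum	R	69.49	I	M	25	67	26
S010	R	R pons	R	2.18	I	M	18	77	15
S011	R	R periventricular DWM, R PLIC	R	4.77	I	M	9	58	41
S012	L	R basal ganglia	R	68.76	H	M	6	48	17
S013	L	L PLIC	L	3.55	I	M	71	59	8
S014	R	R pons	R	1.36	I	M	17	79	35
S015	R	L pons, L caudal midbrain	L	5.43	H	M	21	51	53
S016	R	L corona radiata, L cerebellar hemisphere, L occipital lobe	L	2.44	I	M	5	67	62
S017	R	R basal ganglia	R	60.38	H	M	26	51	13
S018	R	L corona radiata, R pons, L PLEC	L	1.44	I	M	12	66	53
S019	L	R medulla, cerebellum	R	39.26	I	F	8	27	61
S020	R	L pons	L	1.01	I	M	3	53	52
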