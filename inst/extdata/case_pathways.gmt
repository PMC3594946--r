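cytokines and inflammatory response	synthetic fixture pathway	CSF2	TNF	IL2	IL4	IL6	IL10	IL5	IL8
free radical-induced apoptosis	synthetic fixture pathway	TNF	IL6	CASP3	BCL2	TP53	SOD1
cytokine network	synthetic fixture pathway	IL2	IL4	IL5	IL6	IL8	IL10	IL13	IFNG	TGFB1
background metabolism a	synthetic fixture pathway	T007	T008	T009	T010	T011	T012	T013	T014	T015	T016	T017	T018	T019	T020	T021	T022	T023	T024	T025	T026	T027	T028	T029	T030	U001	U002	U003	U004	U005	U006	U007	U008	U009	U010	U011	U012	U013	U014	U015	U016	U017	U018	U019	U020	U021	U022	U023	U024	U025	U026	U027	U028	U029	U030	U031	U032	U033	U034	U035	U036	U037	U038	U039	U040
background metabolism b	synthetic fixture pathway	T031	T032	T033	T034	T035	T036	T037	T038	T039	T040	T041	T042	T043	T044	T045	T046	T047	T048	T049	T050	T051	T052	T053	T054	T055	U041	U042	U043	U044	U045	U046	U047	U048	U049	U050	U051	U052	U053	U054	U055	U056	U057	U058	U059	U060	U061	U062	U063	U064	U065	U066	U067	U068	U069	U070	U071	U072	U073	U074	U075	U076	U077	U078	U079	U080
background transport	synthetic fixture pathway	T056	T057	T058	T059	T060	T061	T062	T063	T064	T065	T066	T067	T068	T069	T070	T071	T072	T073	T074	T075	T076	T077	T078	U081	U082	U083	U084	U085	U086	U087	U088	U089	U090	U091	U092	U093	U094	U095	U096	U097	U098	U099	U100	U101	U102	U103	U104	U105	U106	U107	U108	U109	U110	U111	U112	U113	U114	U115	U116	U117	U118	U119	U120
background signalling	synthetic fixture pathway	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012	S013	S014	S015	K001	K002	K003	K004	K005	K006	K007	K008	K009	K010	K011	K012	K013	K014	K015	U121	U122	U123	U124	U125	U126	U127	U128	U129	U130	U131	U132	U133	U134	U135	U136	U137	U138	U139	U140	U141	U142	U143	U144	U145	U146	U147	U148	U149	U150	U151	U152	U153	U154	U155	U156	U157	U158	U159	U160
background development	synthetic fixture pathway	D001	D002	D003	D004	D005	D006	D007	D008	D009	D010	D011	D012	D013	D014	D015	D016	D017	D018	D019	D020	D021	D022	D023	D024	D025	D026	U161	U162	U163	U164	U165	U166	U167	U168	U169	U170	U171	U172	U173	U174	U175	U176	U177	U178	U179	U180	U181	U182	U183	U184	U185	U186	U187	U188	U189	U190	U191	U192	U193	U194	U195	U196	U197	U198	U199	U200
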