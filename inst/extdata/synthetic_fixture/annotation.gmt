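RAND:0001	random background term 1	g0040	g0031	g0127	g0028	g0061	g0130	g0136	g0044	g0022	g0121	g0089	g0054	g0045	g0062	g0041	g0141	g0066	g0087	g0088	g0119
RAND:0002	random background term 2	g0127	g0089	g0076	g0038	g0053	g0010	g0104	g0112	g0106	g0100	g0095	g0094	g0101	g0058	g0063	g0021	g0005	g0049	g0079	g0061	g0099	g0029	g0103	g0107
RAND:0003	random background term 3	g0116	g0011	g0052	g0099	g0084	g0097	g0014	g0033	g0013	g0030	g0096	g0091	g0135	g0057	g0046	g0073	g0061	g0101	g0018	g0140	g0075
RAND:0004	random background term 4	g0002	g0006	g0122	g0038	g0073	g0086	g0004	g0078	g0040	g0090	g0052	g0032	g0084	g0039	g0033	g0046	g0059	g0083	g0001
RAND:0005	random background term 5	g0083	g0066	g0010	g0146	g0098	g0079	g0021	g0137	g0019	g0069	g0107	g0052	g0084	g0126	g0086	g0082	g0090	g0032	g0048
RAND:0006	random background term 6	g0140	g0039	g0080	g0125	g0042	g0091	g0116	g0122	g0143	g0067	g0141	g0001	g0117	g0055	g0121	g0127	g0103	g0020	g0071	g0009
RAND:0007	random background term 7	g0080	g0037	g0138	g0099	g0035	g0029	g0101	g0142	g0105	g0112	g0067	g0048	g0033	g0089	g0065	g0082	g0039	g0054	g0122	g0135	g0128	g0108	g0110	g0148	g0118
RAND:0008	random background term 8	g0054	g0034	g0045	g0025	g0016	g0129	g0114	g0043	g0047	g0088	g0037	g0068	g0106	g0014	g0009	g0100	g0134	g0033	g0107	g0076	g0128	g0002	g0035
RAND:0009	random background term 9	g0120	g0009	g0037	g0119	g0042	g0051	g0031	g0107	g0087
RAND:0010	random background term 10	g0141	g0093	g0014	g0119	g0012	g0137	g0034	g0051	g0022	g0086	g0134	g0094	g0017	g0084	g0139	g0038	g0003	g0068	g0147	g0149	g0138	g0060	g0072
RAND:0011	random background term 11	g0103	g0107	g0102	g0109	g0136	g0144	g0039	g0093	g0034	g0047	g0127	g0098	g0009	g0004	g0030	g0017	g0068	g0097	g0036	g0026	g0010	g0143	g0061
RAND:0012	random background term 12	g0003	g0105	g0076	g0023	g0145	g0041	g0132	g0138	g0038	g0124	g0101	g0067	g0051	g0128	g0036	g0113	g0137	g0033	g0129	g0016	g0120	g0109
RAND:0013	random background term 13	g0039	g0012	g0064	g0019	g0068	g0136	g0120	g0033	g0053	g0026	g0001	g0124	g0099
RAND:0014	random background term 14	g0060	g0066	g0043	g0047	g0141	g0010	g0003	g0011	g0127	g0144	g0103	g0104	g0055
RAND:0015	random background term 15	g0137	g0061	g0012	g0117	g0105	g0088	g0065	g0142	g0021	g0114	g0101	g0120	g0085	g0083	g0013	g0124	g0145	g0034	g0033	g0041	g0074	g0108
RAND:0016	random background term 16	g0117	g0115	g0044	g0020	g0045	g0150	g0073	g0039	g0085	g0050	g0078	g0069	g0091	g0118	g0025	g0068	g0011	g0010	g0066	g0019	g0018	g0095	g0099
RAND:0017	random background term 17	g0075	g0037	g0009	g0146	g0046	g0140	g0030	g0122	g0007	g0144	g0050	g0045
RAND:0018	random background term 18	g0007	g0136	g0013	g0105	g0003	g0028	g0002	g0137	g0146	g0012	g0073	g0029	g0133	g0095	g0128	g0047	g0131	g0016
RAND:0019	random background term 19	g0129	g0010	g0036	g0148	g0063	g0008	g0068	g0126	g0044	g0083	g0066	g0102
RAND:0020	random background term 20	g0013	g0097	g0063	g0019	g0027	g0105	g0015	g0145	g0103	g0143	g0006	g0023	g0085	g0036	g0124	g0005	g0033	g0099	g0125	g0020	g0055	g0116	g0044
RAND:0021	random background term 21	g0132	g0103	g0075	g0147	g0092	g0025	g0014	g0086	g0008	g0012	g0121	g0049	g0022	g0031	g0066	g0035	g0143	g0042	g0082	g0044	g0007	g0015	g0045
RAND:0022	random background term 22	g0057	g0005	g0074	g0150	g0106	g0113	g0026	g0021	g0012	g0020	g0140	g0060	g0079	g0011	g0129	g0100	g0135	g0033	g0093	g0111	g0053	g0092	g0015	g0031
RAND:0023	random background term 23	g0085	g0107	g0144	g0096	g0007	g0018	g0045	g0128	g0059	g0125
RAND:0024	random background term 24	g0082	g0016	g0049	g0111	g0124	g0130	g0098	g0001	g0054	g0065	g0076
RAND:0025	random background term 25	g0084	g0100	g0076	g0089	g0137	g0001	g0142	g0073	g0028	g0008	g0011
PROG:trans_Hardening_up	planted program term: trans_Hardening up	g0131	g0144	g0092	g0093	g0109	g0095	g0128	g0083	g0098	g0110	g0072	g0079	g0044	g0085	g0058
PROG:trans_Hardening_down	planted program term: trans_Hardening down	g0135	g0139	g0134	g0090	g0148	g0080	g0126	g0146	g0130	g0082	g0142	g0001	g0117	g0147	g0017
PROG:transl_Hardening_up	planted program term: transl_Hardening up	g0099	g0122	g0081	g0145	g0034
PROG:transl_Hardening_down	planted program term: transl_Hardening down	g0107	g0089	g0076	g0117	g0019
PROG:trans_Stress_up	planted program term: trans_Stress up	g0116	g0089	g0087	g0111	g0036
PROG:trans_Stress_down	planted program term: trans_Stress down	g0122	g0123	g0107	g0119	g0067
PROG:transl_Stress_up	planted program term: transl_Stress up	g0096	g0101	g0077	g0130	g0116	g0118	g0087	g0148	g0085	g0146	g0084	g0125	g0059	g0073	g0016
PROG:transl_Stress_down	planted program term: transl_Stress down	g0111	g0088	g0129	g0132	g0143	g0139	g0097	g0075	g0108	g0147	g0123	g0058	g0110	g0064	g0113
PROG:trans_Combo_up	planted program term: trans_Combo up	g0144	g0128	g0083	g0143	g0109	g0078	g0105	g0110	g0095	g0085	g0093	g0080	g0048	g0012	g0037
PROG:trans_Combo_down	planted program term: trans_Combo down	g0126	g0148	g0135	g0090	g0142	g0077	g0129	g0097	g0124	g0130	g0132	g0119	g0024	g0101	g0017
PROG:transl_Combo_up	planted program term: transl_Combo up	g0093	g0115	g0120	g0104	g0144	g0112	g0083	g0131	g0099	g0009
PROG:transl_Combo_down	planted program term: transl_Combo down	g0149	g0114	g0150	g0110	g0100	g0121	g0133	g0104	g0020	g0119
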