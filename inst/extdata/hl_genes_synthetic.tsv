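gene_id	inheritance
HLG0001	DFNA
HLG0002	DFNA
HLG0003	DFNA
HLG0004	DFNA
HLG0005	DFNA
HLG0006	DFNA
HLG0007	DFNA
HLG0008	DFNA
HLG0009	DFNA
HLG0010	DFNA
HLG0011	DFNA
HLG0012	DFNA
HLG0013	DFNA
HLG0014	DFNA
HLG0015	DFNA
HLG0016	DFNA
HLG0017	DFNA
HLG0018	DFNA
HLG0019	DFNA
HLG0020	DFNA
HLG0021	DFNA
HLG0022	DFNA
HLG0023	DFNA
HLG0024	DFNA
HLG0025	DFNA
HLG0026	DFNA
HLG0027	DFNA
HLG0028	DFNA
HLG0029	DFNA
HLG0030	DFNA
HLG0031	DFNA
HLG0032	DFNA
HLG0033	DFNA
HLG0034	DFNA
HLG0035	DFNA
HLG0036	DFNA
HLG0037	DFNA
HLG0038	DFNA
HLG0039	DFNA
HLG0040	DFNA
HLG0041	DFNA
HLG0042	DFNA
HLG0043	DFNA
HLG0044	DFNA
HLG0045	DFNA
HLG0046	DFNA
HLG0047	DFNA
HLG0048	DFNA
HLG0049	DFNA
HLG0050	DFNA
HLG0051	DFNA
HLG0052	DFNA
HLG0053	DFNA
HLG0054	DFNA
HLG0055	DFNA
HLG0056	DFNA
HLG0057	DFNA
HLG0058	DFNA
HLG0059	DFNA
HLG0060	DFNA
HLG0061	DFNA
HLG0062	DFNA
HLG0063	DFNA
HLG0064	DFNA
HLG0065	DFNA
HLG0066	DFNA
HLG0067	DFNB
HLG0068	DFNB
HLG0069	DFNB
HLG0070	DFNB
HLG0071	DFNB
HLG0072	DFNB
HLG0073	DFNB
HLG0074	DFNB
HLG0075	DFNB
HLG0076	DFNB
HLG0077	DFNB
HLG0078	DFNB
HLG0079	DFNB
HLG0080	DFNB
HLG0081	DFNB
HLG0082	DFNB
HLG0083	DFNB
HLG0084	DFNB
HLG0085	DFNB
HLG0086	DFNB
HLG0087	DFNB
HLG0088	DFNB
HLG0089	DFNB
HLG0090	DFNB
HLG0091	DFNB
HLG0092	DFNB
HLG0093	DFNB
HLG0094	DFNB
HLG0095	DFNB
HLG0096	DFNB
HLG0097	DFNB
HLG0098	DFNB
HLG0099	DFNB
HLG0100	DFNB
HLG0101	DFNB
HLG0102	DFNB
HLG0103	DFNB
HLG0104	DFNB
HLG0105	DFNB
HLG0106	DFNB
HLG0107	DFNB
HLG0108	DFNB
HLG0109	DFNB
HLG0110	DFNB
HLG0111	DFNB
HLG0112	DFNB
HLG0113	DFNB
HLG0114	DFNB
HLG0115	DFNB
HLG0116	DFNB
HLG0117	DFNB
HLG0118	DFNB
HLG0119	DFNB
HLG0120	DFNB
HLG0121	DFNB
HLG0122	DFNB
HLG0123	DFNB
HLG0124	DFNB
HLG0125	DFNB
HLG0126	DFNB
HLG0127	DFNB
HLG0128	DFNB
HLG0129	DFNB
HLG0130	DFNB
HLG0131	DFNB
HLG0132	DFNB
HLG0133	DFNB
HLG0134	DFNB
HLG0135	DFNB
HLG0136	DFNB
HLG0137	DFNB
HLG0138	DFNB
HLG0139	DFNB
HLG0140	DFNB
HLG0141	DFNB
HLG0142	DFNB
HLG0143	DFNB
HLG0144	DFNB
HLG0145	DFNB
HLG0146	DFNB
HLG0147	DFNB
HLG0148	DFNB
HLG0149	DFNB
HLG0150	DFNB
HLG0151	DFNB
HLG0152	DFNB
HLG0153	DFNB
HLG0154	DFNB
HLG0155	DFNB
HLG0156	DFNB
HLG0157	DFNB
HLG0158	DFNB
HLG0159	DFNB
HLG0160	DFNB
HLG0161	DFNB
HLG0162	DFNB
HLG0163	DFNB
HLG0164	DFNA+B
HLG0165	DFNA+B
HLG0166	DFNA+B
HLG0167	DFNA+B
HLG0168	DFNA+B
HLG0169	DFNA+B
HLG0170	DFNA+B
HLG0171	DFNA+B
HLG0172	DFNA+B
HLG0173	DFNA+B
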