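sample_id	POP1	POP2	POP3
REF0001	1.000000	0.000000	0.000000
REF0002	0.000000	1.000000	0.000000
REF0003	0.000000	0.000000	1.000000
REF0004	1.000000	0.000000	0.000000
REF0005	0.000000	1.000000	0.000000
REF0006	0.000000	0.000000	1.000000
REF0007	1.000000	0.000000	0.000000
REF0008	0.000000	1.000000	0.000000
REF0009	0.000000	0.000000	1.000000
REF0010	1.000000	0.000000	0.000000
REF0011	0.000000	1.000000	0.000000
REF0012	0.000000	0.000000	1.000000
REF0013	1.000000	0.000000	0.000000
REF0014	0.000000	1.000000	0.000000
REF0015	0.000000	0.000000	1.000000
REF0016	0.198600	0.011400	0.790000
REF0017	0.365200	0.098900	0.535900
REF0018	0.074700	0.304900	0.620400
REF0019	0.107600	0.889600	0.002800
REF0020	0.173700	0.824000	0.002300
REF0021	0.021500	0.000100	0.978400
REF0022	0.506700	0.355700	0.137600
REF0023	0.794400	0.089900	0.115700
REF0024	0.260700	0.529700	0.209600
REF0025	0.810900	0.006500	0.182600
REF0026	0.479452	0.026297	0.494251
REF0027	0.997600	0.000600	0.001800
REF0028	0.000100	0.028800	0.971100
REF0029	0.158316	0.055306	0.786379
REF0030	0.610461	0.256726	0.132813
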