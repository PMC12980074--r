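sample_id	POP1	POP2	POP3
QRY0001	0.842676	0.142795	0.014529
QRY0002	0.411265	0.183005	0.405730
QRY0003	0.349638	0.632671	0.017691
QRY0004	0.547086	0.429512	0.023402
QRY0005	0.704805	0.280062	0.015133
QRY0006	0.115770	0.235750	0.648480
QRY0007	0.179542	0.749743	0.070715
QRY0008	0.722816	0.137593	0.139591
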