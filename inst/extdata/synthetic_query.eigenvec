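#FID IID PC1 PC2 PC3 PC4
FAM1 QRY0001 -5.1773 4.5115 -2.1088 -0.5451
FAM1 QRY0002 -2.4217 1.8462 -3.0845 -1.2139
FAM1 QRY0003 -4.5513 -1.5205 -5.8412 -1.3722
FAM1 QRY0004 -3.9927 1.7214 -5.1515 -2.6920
FAM1 QRY0005 -4.1874 4.3487 -5.3628 -0.7469
FAM1 QRY0006 -3.1044 -0.1090 -1.9902 -0.5973
FAM1 QRY0007 -3.8251 -2.2700 -6.9652 -0.9052
FAM1 QRY0008 -6.0512 6.1976 -3.6319 -0.8046
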