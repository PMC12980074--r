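#FID IID PC1 PC2 PC3 PC4
FAM1 REF0001 -4.4506 7.1438 -3.6168 -0.3312
FAM1 REF0002 -3.6678 -6.4646 -7.7931 -2.5831
FAM1 REF0003 -0.1845 -0.4614 -0.1113 -0.6234
FAM1 REF0004 -5.5332 7.7563 -3.5881 0.4594
FAM1 REF0005 -2.7146 -5.4073 -7.7562 -2.7739
FAM1 REF0006 -1.2726 2.4327 -0.0343 0.1461
FAM1 REF0007 -4.5204 8.5333 -2.2283 -1.2732
FAM1 REF0008 -2.0785 -4.5100 -8.4049 -1.5340
FAM1 REF0009 -2.0822 1.2774 0.3087 0.7786
FAM1 REF0010 -5.5921 6.5846 -3.2166 -1.1735
FAM1 REF0011 -3.0393 -5.8723 -8.8897 -2.4175
FAM1 REF0012 -1.2778 1.6465 0.3681 0.0063
FAM1 REF0013 -5.8742 9.3130 -2.3776 -1.2124
FAM1 REF0014 -2.0029 -5.6585 -8.0378 -1.4421
FAM1 REF0015 -2.4419 0.4513 -0.2288 0.9168
FAM1 REF0016 -3.4309 1.6991 -1.3863 -0.3211
FAM1 REF0017 -4.5911 0.9892 -2.5228 -0.5819
FAM1 REF0018 -1.8362 -1.0973 -3.0168 -0.5638
FAM1 REF0019 -3.9008 -5.4191 -6.9767 -2.5107
FAM1 REF0020 -2.3847 -4.0774 -7.0995 -2.2876
FAM1 REF0021 -3.5048 1.4802 -0.3770 -0.1554
FAM1 REF0022 -5.9025 3.0660 -3.6324 -1.4955
FAM1 REF0023 -5.1576 6.7375 -1.0292 -0.6323
FAM1 REF0024 -2.6891 -0.1564 -4.7065 -1.7448
FAM1 REF0025 -4.9513 6.2984 -3.0062 -0.6406
FAM1 REF0026 -4.1450 4.0494 -0.3400 -0.5706
FAM1 REF0027 -5.6262 7.7673 -1.5845 -1.0237
FAM1 REF0028 -2.2480 -0.3626 -0.7482 -0.6751
FAM1 REF0029 -2.4519 0.8257 -0.2703 0.0601
FAM1 REF0030 -2.3275 2.3073 -4.5535 -1.1386
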