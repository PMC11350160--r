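wavelength_nm,Hb,HbO2,water,lipid,collagen
600,0.033795,0.0073683,0.0022,0.0015,0.02
610,0.029306,0.0057265,0.0026324,0.0014104,0.018557
620,0.024438,0.0041716,0.0030067,0.0013181,0.017225
630,0.018851,0.00279,0.0032648,0.0012207,0.016114
640,0.013101,0.0016592,0.0033486,0.0011155,0.015336
650,0.0086347,0.00084735,0.0032,0.001,0.015
660,0.006479,0.00039627,0.0028334,0.00087729,0.015187
670,0.0058217,0.00024247,0.0025533,0.00077378,0.015854
680,0.0054228,0.00029626,0.0027364,0.00072162,0.016928
690,0.0047805,0.00046793,0.0037597,0.00075298,0.018334
700,0.0041308,0.00066775,0.006,9e-04,0.02
710,0.0036775,0.00082397,0.0096567,0.0011909,0.021854
720,0.0033648,0.00093661,0.014219,0.001638,0.023838
730,0.0030817,0.0010236,0.019,0.0022496,0.025895
740,0.0029322,0.001103,0.023253,0.0030341,0.027967
750,0.0032351,0.0011927,0.026,0.004,0.03
760,0.0038545,0.0013064,0.026535,0.0048,0.031955
770,0.0034254,0.00144,0.025467,0.0042312,0.033873
780,0.0026079,0.0015855,0.02373,0.003,0.035813
790,0.0020493,0.0017346,0.022263,0.0022365,0.037836
800,0.0017546,0.0018789,0.022,0.0025,0.04
810,0.0016818,0.0020119,0.02365,0.0039766,0.042405
820,0.001714,0.002133,0.027009,0.0059309,0.045309
830,0.0017192,0.0022434,0.031642,0.0073968,0.049011
840,0.0016595,0.002344,0.037117,0.0074085,0.053809
850,0.0015911,0.0024361,0.043,0.005,0.06
860,0.0015618,0.0025204,0.048894,6.2545e-05,0.067705
870,0.0015702,0.0025959,0.054547,1e-06,0.076329
880,0.0016021,0.0026615,0.059743,1e-06,0.085101
890,0.0016436,0.0027161,0.064266,0.0067077,0.093249
900,0.0016809,0.0027585,0.0679,0.03,0.1
910,0.0017028,0.0027876,0.075224,0.06666,0.10486
920,0.0017101,0.0028035,0.11,0.1002,0.10841
930,0.0017064,0.0028061,0.19054,0.11,0.11154
940,0.0016954,0.0027957,0.29418,0.084076,0.11512
950,0.0016809,0.0027723,0.388,0.045,0.12
960,0.0016653,0.0027366,0.44539,0.018225,0.12711
970,0.0016467,0.0026915,0.46492,0.0061731,0.13753
980,0.0016221,0.0026402,0.45158,0.0055086,0.1524
990,0.0015885,0.0025862,0.41372,0.012896,0.17285
1000,0.0015427,0.0025328,0.363,0.025,0.2
1010,0.0014829,0.0024828,0.30979,0.038581,0.23266
1020,0.0014109,0.0024357,0.2587,0.050781,0.26028
1030,0.0013296,0.0023907,0.21292,0.058841,0.27
1040,0.0012421,0.0023466,0.17563,0.06,0.25401
1050,0.0011513,0.0023026,0.15,0.052813,0.22482
1060,0.0010596,0.0022577,0.13819,0.0411,0.2
1070,0.00096767,0.0022121,0.13825,0.03,0.19329
1080,0.00087549,0.0021658,0.14722,0.023473,0.20305
1090,0.00078317,0.0021192,0.16213,0.020778,0.22378
1100,0.00069078,0.0020723,0.18,0.02,0.25
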