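state	utility
11111	1
11112	0.8480000000000001
11113	0.41400000000000003
11121	0.796
11122	0.7250000000000001
11123	0.29100000000000004
11131	0.264
11132	0.19300000000000006
11133	0.028000000000000025
11211	0.883
11212	0.812
11213	0.378
11221	0.76
11222	0.6890000000000001
11223	0.255
11231	0.22799999999999998
11232	0.15700000000000003
11233	-0.008000000000000007
11311	0.556
11312	0.4850000000000001
11313	0.32000000000000006
11321	0.43300000000000005
11322	0.3620000000000001
11323	0.19700000000000006
11331	0.17000000000000004
11332	0.09900000000000009
11333	-0.06599999999999995
12111	0.8150000000000001
12112	0.744
12113	0.31000000000000005
12121	0.6920000000000001
12122	0.621
12123	0.18700000000000006
12131	0.16000000000000003
12132	0.08899999999999997
12133	-0.07599999999999996
12211	0.779
12212	0.7080000000000001
12213	0.274
12221	0.656
12222	0.5850000000000001
12223	0.15100000000000002
12231	0.124
12232	0.05300000000000005
12233	-0.11199999999999999
12311	0.45200000000000007
12312	0.381
12313	0.21600000000000008
12321	0.32900000000000007
12322	0.258
12323	0.09300000000000008
12331	0.06600000000000006
12332	-0.0050000000000000044
12333	-0.16999999999999993
13111	0.43600000000000005
13112	0.3650000000000001
13113	0.20000000000000007
13121	0.31300000000000006
13122	0.2420000000000001
13123	0.07700000000000007
13131	0.050000000000000044
13132	-0.020999999999999908
13133	-0.18599999999999994
13211	0.4
13212	0.32900000000000007
13213	0.16400000000000003
13221	0.277
13222	0.20600000000000007
13223	0.041000000000000036
13231	0.014000000000000012
13232	-0.05699999999999994
13233	-0.22199999999999998
13311	0.34199999999999997
13312	0.271
13313	0.10599999999999998
13321	0.21900000000000003
13322	0.14800000000000008
13323	-0.017000000000000015
13331	-0.04399999999999993
13332	-0.11499999999999988
13333	-0.2799999999999999
21111	0.8500000000000001
21112	0.779
21113	0.3450000000000001
21121	0.7270000000000001
21122	0.656
21123	0.2220000000000001
21131	0.19500000000000006
21132	0.124
21133	-0.040999999999999925
21211	0.8140000000000001
21212	0.7430000000000001
21213	0.30900000000000005
21221	0.6910000000000001
21222	0.6200000000000001
21223	0.18600000000000005
21231	0.15900000000000003
21232	0.08800000000000008
21233	-0.07699999999999996
21311	0.4870000000000001
21312	0.41600000000000004
21313	0.2510000000000001
21321	0.3640000000000001
21322	0.29300000000000004
21323	0.1280000000000001
21331	0.10100000000000009
21332	0.030000000000000027
21333	-0.1349999999999999
22111	0.746
22112	0.675
22113	0.241
22121	0.623
22122	0.552
22123	0.118
22131	0.09099999999999997
22132	0.020000000000000018
22133	-0.14500000000000002
22211	0.7100000000000001
22212	0.639
22213	0.20500000000000007
22221	0.587
22222	0.516
22223	0.08199999999999996
22231	0.05500000000000005
22232	-0.016000000000000014
22233	-0.18099999999999994
22311	0.383
22312	0.31200000000000006
22313	0.14700000000000002
22321	0.26
22322	0.18900000000000006
22323	0.02400000000000002
22331	-0.0030000000000000027
22332	-0.07399999999999995
22333	-0.239
23111	0.3670000000000001
23112	0.29600000000000004
23113	0.13100000000000012
23121	0.2440000000000001
23122	0.17300000000000004
23123	0.008000000000000118
23131	-0.018999999999999906
23132	-0.08999999999999997
23133	-0.2549999999999999
23211	0.33100000000000007
23212	0.2600000000000001
23213	0.09500000000000008
23221	0.20800000000000007
23222	0.13700000000000012
23223	-0.027999999999999914
23231	-0.05499999999999994
23232	-0.1259999999999999
23233	-0.2909999999999999
23311	0.273
23312	0.202
23313	0.03700000000000003
23321	0.15000000000000008
23322	0.07900000000000001
23323	-0.08599999999999997
23331	-0.11299999999999988
23332	-0.18399999999999994
23333	-0.34899999999999987
31111	0.33599999999999997
31112	0.265
31113	0.09999999999999998
31121	0.21300000000000002
31122	0.14200000000000007
31123	-0.02300000000000002
31131	-0.04999999999999993
31132	-0.12099999999999989
31133	-0.2859999999999999
31211	0.29999999999999993
31212	0.22900000000000004
31213	0.06399999999999995
31221	0.177
31222	0.10600000000000004
31223	-0.05900000000000005
31231	-0.08599999999999997
31232	-0.15699999999999992
31233	-0.32199999999999995
31311	0.242
31312	0.17100000000000004
31313	0.006000000000000005
31321	0.119
31322	0.04800000000000004
31323	-0.11699999999999999
31331	-0.14400000000000002
31332	-0.21499999999999997
31333	-0.38
32111	0.2320000000000001
32112	0.16099999999999998
32113	-0.0040000000000000036
32121	0.10900000000000004
32122	0.03799999999999998
32123	-0.127
32131	-0.15399999999999991
32132	-0.22499999999999998
32133	-0.3899999999999999
32211	0.196
32212	0.12500000000000006
32213	-0.040000000000000036
32221	0.07300000000000001
32222	0.0020000000000000573
32223	-0.16300000000000003
32231	-0.18999999999999995
32232	-0.2609999999999999
32233	-0.42599999999999993
32311	0.138
32312	0.06699999999999995
32313	-0.09799999999999998
32321	0.015000000000000013
32322	-0.05600000000000005
32323	-0.22099999999999997
32331	-0.248
32332	-0.31900000000000006
32333	-0.484
33111	0.122
33112	0.051000000000000045
33113	-0.11399999999999999
33121	-0.0010000000000000009
33122	-0.07199999999999995
33123	-0.237
33131	-0.264
33132	-0.33499999999999996
33133	-0.4999999999999999
33211	0.08599999999999997
33212	0.015000000000000013
33213	-0.15000000000000002
33221	-0.03700000000000003
33222	-0.10799999999999998
33223	-0.273
33231	-0.30000000000000004
33232	-0.371
33233	-0.5359999999999999
33311	0.028000000000000025
33312	-0.04299999999999993
33313	-0.20799999999999996
33321	-0.09499999999999997
33322	-0.16599999999999993
33323	-0.33099999999999996
33331	-0.358
33332	-0.42899999999999994
33333	-0.594
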