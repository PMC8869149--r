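frame,"x [nm]","y [nm]","intensity [photon]","uncertainty [nm]"
74,-15.6559,36.3809,1031,20
147,-28.6442,-34.4147,1039,20
180,44.3723,15.4142,1048,20
235,-34.1186,-5.60711,1013,20
409,-44.4,-20.9535,975,20
461,0.717919,2.91671,980,20
574,-15.7846,-48.7887,1026,20
695,11.149,-31.7362,1040,20
707,-8.66075,-25.841,973,20
827,-12.0058,-10.1041,1002,20
981,-39.2589,-20.376,1027,20
1001,28.3076,36.4166,1077,20
1038,61.2296,-18.8531,1053,20
1107,13.971,-26.176,1037,20
1112,39.4209,-77.4916,1005,20
1130,-12.3004,-4.15884,988,20
1193,39.3488,20.2896,1006,20
1216,-37.8848,-7.7071,970,20
1317,-4.86595,62.4175,979,20
1326,-10.4839,19.1788,935,20
1350,-4.94848,-41.1104,1033,20
1619,-78.5451,13.5998,969,20
1702,-84.2966,2.1721,980,20
1715,-3.39327,43.3557,999,20
1718,13.4031,24.1098,956,20
1765,-30.4347,26.9403,1004,20
1788,22.4673,-12.7852,930,20
1868,-6.2044,35.6964,1012,20
1969,6.64983,10.1209,973,20
2022,-41.2544,-47.8539,1063,20
2033,-24.8171,11.7795,1050,20
2039,-42.984,-40.4161,979,20
2045,-27.6035,-29.3239,1148,20
2099,13.7349,-13.3919,1034,20
2214,-31.782,0.387613,977,20
2234,6.28654,-3.69134,1005,20
2276,-4.10559,6.61101,960,20
2368,54.5994,19.8646,995,20
2657,-35.3907,5.95017,1023,20
2737,34.4425,39.4492,1046,20
2835,-16.0186,-39.7537,1007,20
2840,16.189,-24.9781,1043,20
2902,1.85386,-51.3932,995,20
2953,-28.5495,-29.6371,963,20
2963,1.37698,17.9464,982,20
3043,36.2801,18.2631,974,20
3213,4.01678,-42.9065,952,20
3235,-59.9389,-38.5479,957,20
3247,-4.38685,11.8468,1045,20
3302,23.6187,-68.0147,1025,20
3314,7.27961,20.5438,986,20
3337,-35.7279,14.8321,1024,20
3347,37.4962,-32.7928,1014,20
3395,-49.379,-1.95818,955,20
3411,-32.1124,68.8165,999,20
3533,-27.4923,35.648,1014,20
3805,44.0679,32.9669,1014,20
3812,26.8298,8.56764,1007,20
3838,-53.3621,18.2287,952,20
3941,-43.7895,-44.946,976,20
3946,-31.4747,30.7442,982,20
4016,-0.738385,50.0387,1022,20
4038,18.0941,-2.00766,958,20
4042,11.2533,-10.3198,1005,20
4122,11.5604,19.0957,990,20
4208,-22.2059,31.3993,1007,20
4260,-56.8997,-11.7844,1067,20
4366,37.2727,29.7304,1058,20
4547,3.69266,30.4624,982,20
4555,24.4665,-23.5177,1035,20
4715,53.4574,-1.20217,1003,20
4777,28.7328,-53.5951,1063,20
4787,-27.7927,5.38869,1017,20
4848,-68.025,-39.452,991,20
5003,41.2534,-39.6166,1038,20
5127,-18.0525,-13.4621,1036,20
5224,-15.0616,6.07666,1044,20
5278,-23.9467,23.4345,1048,20
5322,-51.011,4.38261,948,20
5382,10.3428,-11.3641,1013,20
5765,51.6404,-36.734,989,20
5841,-26.8839,-32.4255,1023,20
5854,-14.639,-25.8759,978,20
5889,-55.2752,20.6823,961,20
6082,38.1938,26.2565,1001,20
6118,7.44411,-6.68448,934,20
6150,-35.2156,-1.48886,1023,20
6192,37.4014,62.2218,998,20
6226,-6.53036,55.5331,971,20
6306,0.429045,-41.4745,995,20
6359,-48.0198,28.9402,992,20
6365,-20.494,1.04094,958,20
6384,-18.3599,9.32594,948,20
6516,-0.288262,49.9019,1009,20
6548,-37.0006,-30.0699,1017,20
6571,36.2355,23.7382,965,20
6597,36.325,1.84848,958,20
6644,-34.4126,-14.2585,1055,20
6696,-50.7013,-7.32678,1007,20
6703,-36.9865,-21.2687,987,20
6729,-36.3917,-25.2005,1008,20
7037,-32.5456,-38.3983,991,20
7116,-25.9675,62.0073,987,20
7192,-10.7546,46.2613,994,20
7199,12.8854,-10.7106,1010,20
7206,33.0122,51.8243,986,20
7285,11.0536,46.4977,1027,20
7327,16.3251,-3.96899,1006,20
7335,-14.1661,7.64773,962,20
7429,10.9944,-31.5595,943,20
7493,-40.9902,14.6396,976,20
7567,14.7478,7.17038,964,20
7569,-31.3839,-37.7341,1046,20
7577,48.3786,38.9828,987,20
7607,11.6297,57.2726,963,20
7632,-24.7209,-10.208,960,20
7721,-14.864,60.5802,1019,20
7755,-14.4253,-20.3317,1044,20
7942,1.08073,-6.22973,1034,20
7954,15.742,54.6348,965,20
8025,35.8774,-36.298,997,20
8120,39.3154,-17.2284,953,20
8132,36.6082,-2.68193,938,20
8181,-81.3364,7.98701,947,20
8211,33.2454,-31.9329,1015,20
8218,30.915,-8.74356,1045,20
8289,-17.6922,-7.33582,1001,20
8309,1.18212,-18.9383,981,20
8404,-47.8235,-18.8489,988,20
8430,51.4154,-9.62798,1058,20
8514,5.81444,-8.88386,999,20
8514,-47.6599,-14.5352,1026,20
8624,-7.22544,20.9926,995,20
8631,-44.8904,38.8372,990,20
8652,-57.3602,-5.94754,1004,20
8773,-22.9942,52.0572,1004,20
8790,-39.9823,33.7305,1010,20
8874,22.8255,13.1392,993,20
8924,47.7159,32.5281,961,20
9017,20.2446,-45.6146,994,20
9040,-53.8661,0.00896456,1025,20
9093,34.5869,49.7852,974,20
9180,-27.0379,-19.7874,986,20
9319,38.6932,43.0134,984,20
9431,17.0767,-5.79024,986,20
9442,-3.39371,38.0613,992,20
9457,-60.6146,14.0685,1036,20
9484,11.3357,27.6883,983,20
9535,-10.9955,-5.85033,966,20
9621,35.2551,-2.56188,1023,20
9636,-11.3388,-28.5697,975,20
9725,-15.833,-12.8438,987,20
9775,21.9616,7.49836,1015,20
9892,36.5421,35.3556,1026,20
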