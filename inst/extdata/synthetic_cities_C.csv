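unit_id,lat,lon,population,count
u0001,-8.51118972395864,-41.1818998570927,2011,461
u0002,-1.57509502890515,-56.5526242942944,2126,477
u0003,2.67549844494282,-58.7017749162256,1786,400
u0004,3.1826914967576,-36.0583493125475,1533,296
u0005,-28.0319548285699,-71.9857150975144,3577,955
u0006,-22.3883254632784,-38.5826587970789,1021,207
u0007,3.44195472986623,-36.2575334740967,1554,361
u0008,4.69869988715285,-48.9022685306158,1717,384
u0009,4.54618466763617,-57.1709500512013,1624,362
u0010,1.68440515516275,-37.0527891491637,1081,208
u0011,-28.2761597342832,-71.5041140604654,2564,657
u0012,-13.6495936926538,-44.7615717901858,3474,980
u0013,-13.3067965594705,-45.1535358725862,11021,4317
u0014,2.83316304722632,-58.172245605356,3106,862
u0015,-12.0503653056484,-56.1809352831878,1319,213
u0016,-22.3219687506236,-38.0228151167274,9578,3505
u0017,-27.5200125451324,-39.7111810983127,1408,312
u0018,1.6295286117594,-36.6543043067577,1035,202
u0019,2.77569619031835,-57.7396064241553,4963,1496
u0020,4.25924659408427,-48.8503227414465,9218,3316
u0021,-13.6699766226272,-44.9907594462549,18050,8247
u0022,-5.66337416765901,-72.8811210742231,1206,263
u0023,-27.7898875764023,-58.6131489625721,1721,357
u0024,-8.58185579849962,-41.3936285806851,2128,500
u0025,1.71913970554564,-53.4705493753036,2740,665
u0026,3.74296996666495,-56.5899559241825,3570,1011
u0027,-4.78949123036667,-41.7778519535442,1668,361
u0028,-1.52110163135591,-56.1882359223897,1222,237
u0029,2.45180256995313,-65.2649328839488,10222,3760
u0030,-5.87178679896034,-72.5978032196826,1038,182
u0031,-7.73867763935317,-47.3473231446756,5927,1947
u0032,-5.17295030327623,-72.7360149022388,11617,4759
u0033,-11.8786490415625,-57.1634453467696,1162,219
u0034,-7.80034395991469,-46.5395239743926,1906,443
u0035,-15.1053902266989,-41.4513949422289,1523,268
u0036,-22.5262802536796,-38.7636283371861,4357,1272
u0037,2.41090011607214,-59.0226862984242,1387,311
u0038,-9.02078910124417,-41.2346621997316,2038,524
u0039,2.44847176625058,-36.3915413200961,1036,195
u0040,-23.2649326597543,-38.7580899933471,1103,220
u0041,-8.37869397177531,-40.7633401109605,1815,380
u0042,-27.2969919823693,-39.3366473800508,13228,5472
u0043,2.98469259551756,-58.5582190951601,44053,26032
u0044,-28.8963631416627,-71.5107923439512,1949,477
u0045,3.63834472214483,-36.2339321121055,1586,368
u0046,3.93274678556212,-56.2278709232802,2388,607
u0047,-28.4975239166179,-70.9910861974948,1138,243
u0048,-8.76556781718224,-41.5930118452654,9261,3459
u0049,-23.3377175362957,-38.3710816760795,1021,175
u0050,-27.814970880159,-58.2173338138082,3775,1098
u0051,4.62075130863623,-48.3576151096959,11866,4721
u0052,-27.8916958142203,-58.3453993512077,2592,639
u0053,1.39206957300213,-36.311049530628,8007,2800
u0054,-1.6176151677901,-56.6430998444082,1720,389
u0055,-30.0487541360949,-48.7833173453677,4165,1203
u0056,-2.04053512629728,-55.7039700401748,1386,282
u0057,-5.14718043613147,-42.2343510581802,6853,2390
u0058,-6.39195318787165,-73,6543,2154
u0059,-27.5635326757447,-71.3143276435011,3858,1136
u0060,2.02755316921287,-64.9349724312174,1286,263
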