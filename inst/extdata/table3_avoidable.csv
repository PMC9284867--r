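category,medicine_code,year,avoidable_expenditure,additional_units,benchmark_category
ME,anastrozole_1,2013,310500,235227,MH
ME,anastrozole_1,2014,350880,265818,MH
ME,anastrozole_1,2015,58597,48030,MH
ME,anastrozole_1,2016,268443,221854,MH
ME,anastrozole_1,2017,83946,68249,MH
ME,anastrozole_1,2019,387309,1046781,OI
ME,docetaxel_40,2013,390477,4067,OI
ME,docetaxel_40,2015,768635,12397,OI
ME,docetaxel_40,2017,552559,7467,MH
ME,docetaxel_40,2018,391184,5927,MH
ME,docetaxel_40,2019,10923,155,MD
ME,exemestane_25,2013,260230,15536,MH
ME,exemestane_25,2015,241621,13240,MH
ME,exemestane_25,2016,117260,6013,OI
ME,exemestane_25,2017,27111,1276,OI
ME,exemestane_25,2018,101956,5826,MH
ME,exemestane_25,2019,126217,28048,MH
ME,letrozole_2.5,2015,80412,12092,MH
ME,letrozole_2.5,2016,539006,56001,OI
ME,letrozole_2.5,2018,340783,54525,MH
ME,paclitaxel_6,2013,301885,173497,MH
ME,paclitaxel_6,2015,1672640,1161556,MH
ME,paclitaxel_6,2016,712742,329973,MD
ME,paclitaxel_6,2019,1212257,396162,MH
ME,tamoxifen_20,2013,271405,678513,MH
ME,tamoxifen_20,2015,2451137,4085228,MH
ME,tamoxifen_20,2017,1158080,1447600,MH
ME,trastuzumab_440,2013,3131527,295,OI
ME,trastuzumab_440,2014,920266,90,OI
ME,trastuzumab_440,2015,1304827,131,OI
ME,trastuzumab_440,2016,328739,32,OI
ME,trastuzumab_440,2017,1506941,144,OI
ME,trastuzumab_440,2018,3185909,315,MH
ME,trastuzumab_440,2019,843025,100,MD
ME,vinorelbine_10,2013,97010,3789,MH
ME,vinorelbine_10,2014,188306,8559,MH
ME,vinorelbine_10,2015,153513,6823,MH
ME,vinorelbine_10,2016,48856,1816,MH
ME,vinorelbine_10,2017,230746,8125,MH
ME,vinorelbine_10,2018,506126,20574,MH
ME,vinorelbine_10,2019,49657,2104,MH
ME,vinorelbine_20,2013,41334,304,MD
ME,vinorelbine_20,2014,14394,114,MD
ME,vinorelbine_20,2015,27455,242,MH
ME,vinorelbine_20,2016,20011,170,MD
ME,vinorelbine_20,2017,61538,531,MD
ME,vinorelbine_20,2018,21901,185,MH
ME,vinorelbine_20,2019,51889,504,MD
ME,vinorelbine_30,2013,107430,567,MD
ME,vinorelbine_30,2014,41584,219,MD
ME,vinorelbine_30,2015,63109,370,MH
ME,vinorelbine_30,2016,92181,539,MH
ME,vinorelbine_30,2017,148594,869,MD
ME,vinorelbine_30,2018,48123,271,MD
ME,vinorelbine_30,2019,273096,1908,OI
MH,anastrozole_1,2018,82660,99591,ME
MH,anastrozole_1,2019,99310,268405,OI
MH,docetaxel_40,2013,3247794,33831,OI
MH,docetaxel_40,2014,147224,2217,ME
MH,docetaxel_40,2015,206006,3323,OI
MH,docetaxel_40,2016,64661,913,ME
MH,exemestane_25,2016,96606,4954,OI
MH,exemestane_25,2017,96196,4527,OI
MH,letrozole_2.5,2013,1362,164,ME
MH,letrozole_2.5,2017,230,25,ME
MH,letrozole_2.5,2019,16162,5213,ME
MH,paclitaxel_6,2014,5711,2884,ME
MH,paclitaxel_6,2016,61613,28525,MD
MH,paclitaxel_6,2017,171549,58350,ME
MH,paclitaxel_6,2018,1068095,468463,ME
MH,tamoxifen_20,2016,1285271,918051,ME
MH,trastuzumab_440,2013,8496516,801,OI
MH,trastuzumab_440,2014,4553299,447,OI
MH,trastuzumab_440,2015,2594719,260,OI
MH,trastuzumab_440,2017,3746929,358,OI
MH,trastuzumab_440,2019,570309,67,MD
MH,vinorelbine_20,2013,31586,232,MD
MH,vinorelbine_20,2016,10337,88,MD
MH,vinorelbine_20,2017,36843,318,MD
MH,vinorelbine_20,2019,48881,475,MD
MH,vinorelbine_30,2013,240228,1267,MD
MH,vinorelbine_30,2017,62664,366,MD
MH,vinorelbine_30,2018,1021,6,MD
MH,vinorelbine_30,2019,112578,787,OI
MD,anastrozole_1,2013,175371,132857,MH
MD,anastrozole_1,2014,301078,228090,MH
MD,anastrozole_1,2015,364487,298759,MH
MD,anastrozole_1,2016,71568,59147,MH
MD,anastrozole_1,2017,1160270,943309,MH
MD,anastrozole_1,2018,229449,276445,ME
MD,anastrozole_1,2019,185286,500773,OI
MD,docetaxel_40,2013,28038,292,OI
MD,docetaxel_40,2014,159722,2405,ME
MD,docetaxel_40,2015,945109,15244,OI
MD,docetaxel_40,2016,81561,1152,ME
MD,docetaxel_40,2017,592045,8001,MH
MD,docetaxel_40,2018,1118551,16948,MH
MD,exemestane_25,2013,219671,13115,MH
MD,exemestane_25,2014,13113,656,ME
MD,exemestane_25,2015,96936,5312,MH
MD,exemestane_25,2016,65326,3350,OI
MD,exemestane_25,2017,156005,7341,OI
MD,exemestane_25,2018,121042,6917,MH
MD,exemestane_25,2019,572184,127152,MH
MD,letrozole_2.5,2013,4687,563,ME
MD,letrozole_2.5,2014,40085,5257,ME
MD,letrozole_2.5,2015,82559,12415,MH
MD,letrozole_2.5,2016,26446,2748,OI
MD,letrozole_2.5,2017,83644,8946,ME
MD,letrozole_2.5,2018,244233,39077,MH
MD,letrozole_2.5,2019,318416,102715,ME
MD,paclitaxel_6,2013,193477,111194,MH
MD,paclitaxel_6,2014,1335805,674649,ME
MD,paclitaxel_6,2015,249584,173322,MH
MD,paclitaxel_6,2017,79445,27022,ME
MD,paclitaxel_6,2018,325684,142844,ME
MD,paclitaxel_6,2019,337189,110193,MH
MD,tamoxifen_20,2013,72358,180896,MH
MD,tamoxifen_20,2014,31192,51986,MH
MD,tamoxifen_20,2015,295977,493295,MH
MD,tamoxifen_20,2016,22452,16037,ME
MD,tamoxifen_20,2017,97743,122179,MH
MD,tamoxifen_20,2018,76082,95103,MH
MD,trastuzumab_440,2013,3269234,308,OI
MD,trastuzumab_440,2014,4268039,419,OI
MD,trastuzumab_440,2015,4736421,475,OI
MD,trastuzumab_440,2016,639984,62,OI
MD,trastuzumab_440,2017,6876263,657,OI
MD,trastuzumab_440,2018,1407957,139,MH
MD,vinorelbine_10,2013,9412,368,MH
MD,vinorelbine_10,2014,65409,2973,MH
MD,vinorelbine_10,2015,36320,1614,MH
MD,vinorelbine_10,2016,8213,305,MH
MD,vinorelbine_10,2017,30110,1060,MH
MD,vinorelbine_10,2018,33388,1357,MH
MD,vinorelbine_10,2019,57289,2427,MH
MD,vinorelbine_20,2015,33911,299,MH
MD,vinorelbine_20,2018,323,3,MH
MD,vinorelbine_30,2015,19258,113,MH
MD,vinorelbine_30,2016,2632,15,MH
MD,vinorelbine_30,2019,41251,288,OI
OI,anastrozole_1,2013,273649,207310,MH
OI,anastrozole_1,2014,148643,112608,MH
OI,anastrozole_1,2015,215818,176900,MH
OI,anastrozole_1,2016,456011,376868,MH
OI,anastrozole_1,2017,76409,62121,MH
OI,anastrozole_1,2018,218657,263442,ME
OI,docetaxel_40,2014,213948,3222,ME
OI,docetaxel_40,2016,2007159,28350,ME
OI,docetaxel_40,2017,322482,4358,MH
OI,docetaxel_40,2018,491028,7440,MH
OI,exemestane_25,2013,15042,898,MH
OI,exemestane_25,2014,28088,1404,ME
OI,exemestane_25,2015,36445,1997,MH
OI,exemestane_25,2018,280207,16012,MH
OI,exemestane_25,2019,610704,135712,MH
OI,letrozole_2.5,2013,49663,5966,ME
OI,letrozole_2.5,2014,1082,142,ME
OI,letrozole_2.5,2015,3500,526,MH
OI,letrozole_2.5,2017,108797,11636,ME
OI,letrozole_2.5,2018,4065,650,MH
OI,letrozole_2.5,2019,5913,1907,ME
OI,paclitaxel_6,2013,411748,236637,MH
OI,paclitaxel_6,2014,245363,123921,ME
OI,paclitaxel_6,2015,362000,251389,MH
OI,paclitaxel_6,2016,39448,18263,MD
OI,paclitaxel_6,2017,263379,89585,ME
OI,paclitaxel_6,2018,404387,177363,ME
OI,paclitaxel_6,2019,104450,34134,MH
OI,tamoxifen_20,2013,568902,1422254,MH
OI,tamoxifen_20,2014,918086,1530144,MH
OI,tamoxifen_20,2015,213870,356450,MH
OI,tamoxifen_20,2016,168534,120382,ME
OI,tamoxifen_20,2018,140916,176146,MH
OI,trastuzumab_440,2018,1050590,104,MH
OI,trastuzumab_440,2019,1996514,236,MD
OI,vinorelbine_10,2013,3422,134,MH
OI,vinorelbine_10,2014,34022,1546,MH
OI,vinorelbine_10,2015,7198,320,MH
OI,vinorelbine_10,2016,28195,1048,MH
OI,vinorelbine_10,2017,428934,15103,MH
OI,vinorelbine_10,2018,114889,4670,MH
OI,vinorelbine_10,2019,73749,3125,MH
OI,vinorelbine_20,2019,22812,221,MD
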