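species_id,order,family,subfamily,tribe,genus,continent,invasive,flags,ldt_c,set_dd
P001_N,order_01,family_01,NA,NA,genus_001,Europe,0,,9.484,533.3
P002_N,order_02,family_02,NA,NA,genus_002,Europe,0,,9.344,NA
P003_N,order_03,family_03,NA,NA,genus_003,North_America,0,,10.644,562.9
P004_N,order_04,family_04,NA,NA,genus_004,Oceania,0,,9.718,315.3
P005_N,order_05,family_05,NA,NA,genus_005,Europe,0,,10.045,NA
P006_N,order_01,family_06,NA,NA,genus_006,Europe,0,,11.253,NA
P007_N,order_02,family_07,NA,NA,genus_007,Europe,0,,5.31,445.6
P008_N,order_03,family_08,NA,NA,genus_008,Asia,0,,12.481,724
P009_N,order_04,family_09,NA,NA,genus_009,North_America,0,,7.525,282.8
P010_N,order_05,family_10,NA,NA,genus_010,North_America,0,,6.383,658.1
P011_N,order_01,family_11,NA,NA,genus_011,North_America,0,,6.591,314.3
P012_N,order_02,family_12,NA,NA,genus_012,North_America,0,,4.623,137.7
P013_N,order_03,family_13,NA,NA,genus_013,Europe,0,,10.089,NA
P014_N,order_04,family_14,NA,NA,genus_014,North_America,0,,6.783,395
P015_N,order_05,family_15,NA,NA,genus_015,Europe,0,,9.023,409.8
P016_N,order_01,family_16,NA,NA,genus_016,Oceania,0,,11.236,863.1
P017_N,order_02,family_17,NA,NA,genus_017,North_America,0,,11.503,301.3
P018_N,order_03,family_18,NA,NA,genus_018,North_America,0,,12.882,352.2
P019_N,order_04,family_19,NA,NA,genus_019,North_America,0,,16.502,618
P020_N,order_05,family_20,NA,NA,genus_020,Asia,0,,3.861,522
P001_I,order_01,family_01,NA,NA,genus_001,Europe,1,,15.265,330.7
P002_I,order_02,family_02,NA,NA,genus_002,Europe,1,,8.939,NA
P003_I,order_03,family_03,NA,NA,genus_003,North_America,1,,13.205,459.2
P004_I,order_04,family_04,NA,NA,genus_004,Oceania,1,,13.141,516.8
P005_I,order_05,family_05,NA,NA,genus_005,Europe,1,,12.737,NA
P006_I,order_01,family_06,NA,NA,genus_006,Europe,1,,12.314,NA
P007_I,order_02,family_07,NA,NA,genus_007,Europe,1,,11.541,245.1
P008_I,order_03,family_08,NA,NA,genus_008,Asia,1,,13.578,280
P009_I,order_04,family_09,NA,NA,genus_009,North_America,1,,15.377,215.6
P010_I,order_05,family_10,NA,NA,genus_010,North_America,1,,7.583,473.8
P011_I,order_01,family_11,NA,NA,genus_011,North_America,1,,12.161,293.8
P012_I,order_02,family_12,NA,NA,genus_012,North_America,1,,13.331,109.6
P013_I,order_03,family_13,NA,NA,genus_013,Europe,1,,7.05,NA
P014_I,order_04,family_14,NA,NA,genus_014,North_America,1,,7.292,232.4
P015_I,order_05,family_15,NA,NA,genus_015,Europe,1,,9.997,497.1
P016_I,order_01,family_16,NA,NA,genus_016,Oceania,1,,14.669,381
P017_I,order_02,family_17,NA,NA,genus_017,North_America,1,,11.995,98.2
P018_I,order_03,family_18,NA,NA,genus_018,North_America,1,,5.791,292.4
P019_I,order_04,family_19,NA,NA,genus_019,North_America,1,,10.102,179.3
P020_I,order_05,family_20,NA,NA,genus_020,Asia,1,,9.48,402.8
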