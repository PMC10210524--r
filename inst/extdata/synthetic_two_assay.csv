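id,Y,W,M
S001,0,3.5034,2.9145
S002,0,3.8806,3.4508
S003,0,3.8501,3.0193
S004,0,3.2111,4.3643
S005,0,3.4812,4.6778
S006,0,5.3997,4.3536
S007,0,3.0504,3.5534
S008,0,4.0359,4.8196
S009,0,3.3471,2.6686
S010,0,2.8141,2.0907
S011,0,3.4761,3.1682
S012,0,4.2035,4.3538
S013,0,3.6988,5.1669
S014,0,4.2355,3.6246
S015,0,1.7201,0.1152
S016,0,3.2293,4.2058
S017,0,3.9888,4.968
S018,0,3.0036,1.4255
S019,0,2.4164,3.0254
S020,0,3.4906,3.4692
S021,0,1.5164,2.4178
S022,0,3.6986,4.7697
S023,0,4.2255,4.668
S024,0,4.1671,4.0359
S025,0,4.5201,6.4724
S026,0,2.3559,2.2151
S027,0,1.9151,0.474
S028,0,2.0886,2.6233
S029,0,3.8934,1.7589
S030,0,3.9412,5.1543
S031,0,2.1889,1.2681
S032,0,2.8865,3.5175
S033,0,3.02,2.7496
S034,0,2.8566,2.0592
S035,0,3.6881,5.1965
S036,0,3.755,1.2021
S037,0,3.4817,3.4233
S038,0,2.2009,3.0397
S039,0,4.3875,5.3756
S040,0,3.662,3.1637
S041,0,4.6412,5.0258
S042,0,3.554,2.8747
S043,0,2.6505,2.6501
S044,0,3.5112,3.493
S045,0,3.1272,1.1874
S046,0,1.7621,1.518
S047,0,2.3782,4.822
S048,0,5.0951,4.4598
S049,0,3.0262,2.8705
S050,0,1.9127,2.3826
S051,0,3.2446,5.2992
S052,0,5.0483,4.6368
S053,0,2.26,2.2049
S054,0,3.8549,4.558
S055,0,3.6457,4.9884
S056,0,2.445,2.8152
S057,0,5.0762,5.05
S058,0,4.526,5.4916
S059,0,3.2812,2.3723
S060,0,3.2582,4.0059
S061,0,2.3639,2.5586
S062,0,3.1457,2.4781
S063,0,5.966,4.4398
S064,0,2.4057,3.7137
S065,0,3.2575,3.8111
S066,0,4.4056,4.1381
S067,0,1.9727,2.7292
S068,1,5.5529,6.1537
S069,1,4.5503,5.7492
S070,1,6.5413,6.828
S071,1,1.1925,1.657
S072,1,3.9445,3.2791
S073,1,2.9084,2.6329
S074,1,5.5098,6.3159
S075,1,4.5626,4.9656
S076,1,4.2314,3.6429
S077,1,4.5386,3.5896
S078,1,5.0397,5.7856
S079,1,4.2986,5.2844
S080,1,4.8976,4.3283
S081,1,3.0304,3.663
S082,1,4.2723,5.1453
S083,1,2.4162,1.78
S084,1,5.9769,6.2443
S085,1,3.1546,5.4914
S086,1,4.2953,4.2898
S087,1,4.7,4.7704
S088,1,5.0166,6
S089,1,5.7197,4.3716
S090,1,2.3227,2.2849
S091,1,5.5187,3.6243
S092,1,4.4228,3.1146
S093,1,4.6354,5.7475
S094,1,2.2833,1.3453
S095,1,2.8898,3.0987
S096,1,4.3274,6.1108
S097,1,3.8574,2.3241
S098,1,5.2718,3.6392
S099,1,4.793,7.1922
S100,1,5.5995,4.8762
S101,1,4.8633,4.3596
S102,1,5.2105,4.7569
S103,1,6.2605,8.0356
S104,1,5.5851,6.1372
S105,1,2.4832,2.7054
S106,1,4.3666,5.3191
S107,1,2.9122,3.3369
S108,1,1.6582,2.0419
S109,1,2.6048,2.1676
S110,1,1.1724,0.839
S111,1,2.9669,2.6772
S112,1,4.0799,4.3915
S113,1,4.4445,5.0047
S114,1,3.8656,2.6542
S115,1,4.8592,4.6542
S116,1,4.6827,4.4124
S117,1,5.0169,4.6448
S118,1,4.3968,4.1902
S119,1,4.5778,5.3702
S120,1,3.3107,2.6934
S121,1,2.0296,1.0537
S122,1,3.4501,4.0705
S123,1,4.6842,4.1675
S124,1,4.5932,4.224
S125,1,4.1503,2.2795
S126,1,5.2183,3.9015
S127,1,3.644,2.6758
S128,1,4.8297,3.8733
S129,1,4.5733,3.4948
S130,1,5.1724,6.7198
S131,1,4.9826,4.5876
S132,1,3.8676,3.3016
S133,1,2.4582,3.1091
S134,1,3.7957,2.6992
S135,1,1.9527,1.9795
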