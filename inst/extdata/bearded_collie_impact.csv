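dog_id,total_variants,high_count,pct_homalt_high,moderate_count,pct_homalt_moderate,neutral_count,pct_homalt_neutral
BC1570,7940287,4494,12.9,29435,13.2,7906358,22.9
BC1696,8113127,4505,12.0,29454,13.0,8079168,23.5
BC1838,8145732,4577,12.6,29637,12.6,8111518,23.0
BC1852,8140001,4565,13.1,29554,13.1,8105882,24.2
BC1893,8112085,4527,12.8,29484,14.4,8078074,25.2
BC1894,7990385,4532,13.0,29581,13.2,7956272,22.1
BC1895,8121517,4537,12.8,29525,12.6,8087455,22.6
BC1896,8127437,4550,11.7,29539,12.7,8093348,23.4
BC1899,7964369,4503,11.0,29492,11.8,7930374,20.6
BC1901,8145187,4590,11.9,29633,12.0,8110964,22.6
BC1904,8133943,4553,14.2,29415,13.8,8099975,25.1
BC1905,8130514,4538,13.0,29490,13.0,8096486,22.6
BC1909,8106692,4503,12.5,29362,12.2,8072827,22.4
BC1911,8134998,4576,12.3,29589,12.7,8100833,22.2
BC1916,8138035,4547,11.7,29499,13.0,8103989,23.3
BC1918,8128449,4556,14.6,29449,14.6,8094444,25.6
BC1936,8144075,4597,13.7,29622,13.9,8109856,23.6
BC1943,8109118,4475,11.3,29395,11.3,8075248,20.7
BC1944,8118503,4513,11.5,29506,12.6,8084484,22.1
BC1945,8103332,4450,11.9,29333,13.0,8069549,23.2
BC1952,8142011,4581,13.9,29586,13.8,8107844,24.0
BC0057,8131063,4555,14.6,29531,14.8,8096977,26.0
BC0058,8135341,4584,13.5,29635,13.5,8101122,23.5
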