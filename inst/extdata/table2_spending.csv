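medicine_code,category,expenditure
anastrozole_1,ME,13196020
anastrozole_1,MH,9337267
anastrozole_1,MD,5263653
anastrozole_1,OI,5464512
docetaxel_40,ME,22886244
docetaxel_40,MH,19535557
docetaxel_40,MD,6095049
docetaxel_40,OI,10729355
exemestane_25,ME,16301476
exemestane_25,MH,4857270
exemestane_25,MD,6449958
exemestane_25,OI,4948653
letrozole_2.5,ME,6683805
letrozole_2.5,MH,573524
letrozole_2.5,MD,3549046
letrozole_2.5,OI,1105916
paclitaxel_6,ME,26010194
paclitaxel_6,MH,8515488
paclitaxel_6,MD,4896219
paclitaxel_6,OI,5591795
tamoxifen_20,ME,19865277
tamoxifen_20,MH,9197183
tamoxifen_20,MD,1604663
tamoxifen_20,OI,5589036
trastuzumab_440,ME,79911241
trastuzumab_440,MH,195836172
trastuzumab_440,MD,174182648
trastuzumab_440,OI,285744659
vinorelbine_10,ME,6305699
vinorelbine_10,MH,2153148
vinorelbine_10,MD,814825
vinorelbine_10,OI,1788105
vinorelbine_20,ME,6338358
vinorelbine_20,MH,6429645
vinorelbine_20,MD,2498773
vinorelbine_20,OI,228920
vinorelbine_30,ME,17960731
vinorelbine_30,MH,9193434
vinorelbine_30,MD,4351541
vinorelbine_30,OI,286020
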