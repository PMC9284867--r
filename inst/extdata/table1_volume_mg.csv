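medicine_code,category,volume_mg
anastrozole_1,ME,10838515
anastrozole_1,MH,8803262
anastrozole_1,MD,2913665
anastrozole_1,OI,3722340
docetaxel_40,ME,12097460
docetaxel_40,MH,8352420
docetaxel_40,MD,1834800
docetaxel_40,OI,4304760
exemestane_25,ME,21923725
exemestane_25,MH,7926800
exemestane_25,MD,8587175
exemestane_25,OI,6842850
letrozole_2.5,ME,2109253
letrozole_2.5,MH,196850
letrozole_2.5,MD,1040350
letrozole_2.5,OI,257963
paclitaxel_6,ME,60776655
paclitaxel_6,MH,18113116
paclitaxel_6,MD,5987234
paclitaxel_6,OI,11082205
tamoxifen_20,ME,394563360
tamoxifen_20,MH,205193800
tamoxifen_20,MD,26791300
tamoxifen_20,OI,92260920
trastuzumab_440,ME,3030720
trastuzumab_440,MH,7537200
trastuzumab_440,MD,6787880
trastuzumab_440,OI,12208240
vinorelbine_10,ME,2058470
vinorelbine_10,MH,854040
vinorelbine_10,MD,233700
vinorelbine_10,OI,415870
vinorelbine_20,ME,1047080
vinorelbine_20,MH,1063520
vinorelbine_20,MD,428380
vinorelbine_20,OI,40000
vinorelbine_30,ME,3007350
vinorelbine_30,MH,1512930
vinorelbine_30,MD,750600
vinorelbine_30,OI,60000
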