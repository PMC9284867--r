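medicine_code,name,strength_mg,dosage_form
anastrozole_1,Anastrozole,1,tablet
docetaxel_40,Docetaxel,40,ampoule
exemestane_25,Exemestane,25,capsule
letrozole_2.5,Letrozole,2.5,tablet
paclitaxel_6,Paclitaxel,6,ampoule
tamoxifen_20,Tamoxifen,20,tablet
trastuzumab_440,Trastuzumab,440,ampoule
vinorelbine_10,Vinorelbine,10,ampoule
vinorelbine_20,Vinorelbine,20,ampoule
vinorelbine_30,Vinorelbine,30,ampoule
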