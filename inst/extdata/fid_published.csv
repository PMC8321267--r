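subset,preprocessing,pair,fid
EDRA,none,macro_dermo,167.9
EDRA,none,macro_transmacro,160.2
EDRA,none,dermo_transdermo,186.4
SMARTSKINS 2014/2015,uncropped,macro_dermo,331.7
SMARTSKINS 2014/2015,uncropped,macro_transmacro,285.1
SMARTSKINS 2014/2015,uncropped,dermo_transdermo,285.6
SMARTSKINS 2014/2015,cropped,macro_dermo,294.2
SMARTSKINS 2014/2015,cropped,macro_transmacro,177.5
SMARTSKINS 2014/2015,cropped,dermo_transdermo,263.6
ISIC (Set D),none,macro_dermo,180.9
ISIC (Set D),none,macro_transmacro,123.7
PH2 (Set D),cropped,macro_dermo,292.9
PH2 (Set D),cropped,macro_transmacro,285.7
segmentation sets,none,setM_setD,181.1
segmentation sets,none,setM_setMartificial,102.4
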