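species,n
Artocarpus altilis,187
Canna sp.,81
Colocasia esculenta,121
Curcuma longa,94
Dioscorea alata,100
Inocarpus fagifer,59
Ipomoea batatas,103
Manihot esculenta,71
Musa sp.,71
Spondias dulcis,97
Triticum aestivum,78
Xanthosoma sp.,80
Zingiber officinale,98
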