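species,n
Artocarpus altilis,200
Canna sp.,100
Colocasia esculenta,200
Curcuma longa,100
Dioscorea alata,100
Inocarpus fagifer,100
Ipomoea batatas,200
Manihot esculenta,100
Musa sp.,100
Spondias dulcis,100
Xanthosoma sp.,98
Zingiber officinale,100
Triticum aestivum,100
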