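"taxon","pfts","arboreal","dwarf_shrub","vine","productivity"
"Pinus","boreal_conifer",TRUE,FALSE,FALSE,4
"Picea","boreal_conifer",TRUE,FALSE,FALSE,2
"Quercus","temperate_broadleaf",TRUE,FALSE,FALSE,2
"Corylus","temperate_broadleaf",TRUE,FALSE,FALSE,1.5
"Betula","boreal_summergreen,arctic_alpine",TRUE,FALSE,FALSE,3
"Calluna","arctic_alpine",TRUE,TRUE,FALSE,1
"Poaceae","steppe_grass",FALSE,FALSE,FALSE,1.5
"Artemisia","steppe_grass",FALSE,FALSE,FALSE,1
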