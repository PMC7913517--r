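# canonical<TAB>aliases<TAB>flags -- drugs cited in dermatology omics work
imiquimod		
dupilumab		
adalimumab		
ustekinumab		
methotrexate	MTX	
secukinumab		
etanercept		
infliximab		
cyclosporine	ciclosporin,cyclosporin A	
tofacitinib		
ixekizumab		
guselkumab		
brodalumab		
risankizumab		
apremilast		
acitretin		
tacrolimus		
pimecrolimus		
crisaborole		
tralokinumab		
nemolizumab		
baricitinib		
upadacitinib		
abrocitinib		
calcipotriol	calcipotriene	
clindamycin		
rifampicin	rifampin	
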