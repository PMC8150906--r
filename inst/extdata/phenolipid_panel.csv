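# Reference property panel: tyrosol (TY), hydroxytyrosol (HT),
# 4-hydroxycinnamic acid (HCA), caffeic acid (CA) and dihydrocaffeic acid
# (DCA) and their C8/C16 alkyl esters, as measured in 4:6 olive
# oil-in-water emulsions (citrate buffer pH 3.65, Tween 20 emulsifier).
# Columns: first anodic peak potential (V vs Ag/AgCl) at pH 7.4 and 3.65;
# DPPH EC50 (mol AO / mol DPPH) read at 5 and 60 min; FRAP value (uM
# Fe(II) equivalents); water-interface and oil-interface partition
# constants with standard errors (empty = not measurable: probe
# reactivity too low, or region not occupied).
compound,series,chain_length,epa_ph74,epa_ph365,ec50_5,ec50_60,frap,p_wi,p_wi_err,p_oi,p_oi_err
TY,tyrosol,0,0.645,0.798,21,20,54.7,,,,
TY8,tyrosol,8,0.561,0.763,23,23,19.6,,,,
TY16,tyrosol,16,0.583,0.783,23,23,12.5,,,,
HT,hydroxytyrosol,0,0.217,0.411,0.323,0.258,1523,53,7,,
HT8,hydroxytyrosol,8,0.235,0.419,0.295,0.243,1193,,,296,85
HT16,hydroxytyrosol,16,0.222,0.403,0.331,0.268,653,,,52,5
HCA,hydroxycinnamic,0,0.612,0.805,23,21,59.9,,,,
HCA8,hydroxycinnamic,8,0.579,0.760,24,22,56.4,,,39,2
HCA16,hydroxycinnamic,16,0.566,0.787,24,23,54.1,,,36,3
CA,caffeic,0,0.265,0.394,0.330,0.344,1765,204,16,,
CA8,caffeic,8,0.263,0.379,0.293,0.199,1617,,,502,32
CA16,caffeic,16,0.260,0.378,0.317,0.196,1078,,,376,35
DCA,dihydrocaffeic,0,0.157,0.344,0.204,0.149,2921,58,13,,
DCA8,dihydrocaffeic,8,0.155,0.339,0.266,0.267,1613,,,368,29
DCA16,dihydrocaffeic,16,0.150,0.349,0.268,0.270,1513,,,220,54
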