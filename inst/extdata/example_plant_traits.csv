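species,corolla_length,corolla_opening,corolla_curvature
P01,23.9972310092086,4.81249388994391,0.0177856340059383
P02,13.7060933870683,4.41815766042252,0.0177418347557105
P03,20.998806731737,6.2079194128382,0.00546881446128296
P04,19.4154705406206,5.20501286994625,0.0334700149929703
P05,15.837941279396,5.30842434621345,0.0261640814584997
P06,8.29042398799879,4.81930383785045,0.0221756433830789
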