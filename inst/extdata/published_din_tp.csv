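site,din_tp
Eunice,0.7
Hidden MORA,1.5
Snow,0.9
Copper,1.4
Hidden NOCA,2.8
Lower Thornton,3.0
Stiletto,1.6
Heather,2.4
Hoh,0.9
Milk,1.4
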