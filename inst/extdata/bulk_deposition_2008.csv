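site,park,days_deployed,n_columns,nh4_n_rate,nh4_n_sd,no3_n_rate,no3_n_sd,inorganic_n_rate,inorganic_n_sd,so4_s_rate,so4_s_sd
Eunice,MORA,85,5,1.07,0.10,0.91,0.12,1.97,0.19,1.90,0.44
Hidden MORA,MORA,76,5,0.58,0.17,0.49,0.18,1.07,0.34,1.18,0.38
Shriner,MORA,86,1,0.95,,0.56,,1.51,,1.05,
Snow,MORA,71,5,0.51,0.14,0.58,0.12,1.09,0.22,1.45,0.44
Copper,NOCA,66,5,1.06,0.21,1.20,0.11,2.27,0.32,2.28,0.40
Hidden NOCA,NOCA,59,5,1.01,0.07,1.02,0.22,2.02,0.19,1.71,0.58
Lower Thornton,NOCA,72,5,1.10,0.21,1.32,0.19,2.42,0.27,2.10,0.70
Stiletto,NOCA,71,5,0.46,0.41,0.73,0.24,1.19,0.40,1.12,0.27
Heather,OLYM,65,5,0.25,0.15,0.45,0.11,0.70,0.10,0.86,0.49
Hoh,OLYM,68,5,0.49,0.25,0.48,0.15,0.97,0.30,2.33,0.69
Milk,OLYM,80,5,0.49,0.07,0.55,0.12,1.04,0.13,1.31,0.32
PJ,OLYM,60,5,0.25,0.11,0.34,0.04,0.59,0.07,1.25,0.17
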