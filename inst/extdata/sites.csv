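name,park,usgs_id,latitude_deg,longitude_deg,elevation_m,area_ha,max_depth_m
Eunice,MORA,12091956,46.95563,-121.87722,1634,5.32,20
Hidden MORA,MORA,12096700,46.94181,-121.59812,1807,2.12,7
Shriner,MORA,14223825,46.80900,-121.51453,1490,1.67,4
Snow,MORA,14224590,46.75759,-121.69825,1426,2.39,10
Copper,NOCA,12215650,48.91818,-121.45149,1604,5.22,20
Hidden NOCA,NOCA,12181450,48.49583,-121.18885,1747,24.98,79
Lower Thornton,NOCA,12178700,48.68420,-121.32806,1367,22.30,33
Stiletto,NOCA,12450880,48.48197,-120.65632,2071,4.01,26
Heather,OLYM,12047660,47.78508,-123.17788,1589,0.4,7
Hoh,OLYM,12040680,47.89872,-123.78588,1384,7.44,15
Milk,OLYM,12053810,47.62525,-123.20604,1435,1.11,4
PJ,OLYM,12047150,47.96069,-123.42837,1384,0.8,6
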