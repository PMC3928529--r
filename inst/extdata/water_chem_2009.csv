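site,date,analyte,value,qualifier,detection_limit
Eunice,2009-11-04,spec_cond,7.5,,
Eunice,2009-11-04,pH,6.5,,
Eunice,2009-11-04,ANC,30,,
Eunice,2009-11-04,NH4-N,<0.01,,
Eunice,2009-11-04,NO3-N,0.002,,0.001
Eunice,2009-11-04,PO4-P,<0.001,,
Eunice,2009-11-04,TN,0.250,,
Eunice,2009-11-04,TP,0.012,,0.002
Eunice,2009-11-04,Chl-a,0.4,E,
Hidden MORA,2010-08-19,spec_cond,15.8,,
Hidden MORA,2010-08-19,pH,6.7,,
Hidden MORA,2010-08-19,ANC,46,,
Hidden MORA,2010-08-19,NH4-N,<0.01,,
Hidden MORA,2010-08-19,NO3-N,0.001,,0.001
Hidden MORA,2010-08-19,PO4-P,0.001,,0.001
Hidden MORA,2010-08-19,TN,0.060,,
Hidden MORA,2010-08-19,TP,0.004,,0.002
Hidden MORA,2010-08-19,Chl-a,0.7,E,
Snow,2009-10-07,spec_cond,12.9,,
Snow,2009-10-07,pH,5.4,,
Snow,2009-10-07,ANC,10,,
Snow,2009-10-07,NH4-N,<0.01,,
Snow,2009-10-07,NO3-N,<0.001,,
Snow,2009-10-07,PO4-P,<0.001,,
Snow,2009-10-07,TN,0.090,,
Snow,2009-10-07,TP,0.006,,0.002
Snow,2009-10-07,Chl-a,1.51,E,
Copper,2009-09-22,spec_cond,5.6,,
Copper,2009-09-22,pH,6.1,,
Copper,2009-09-22,ANC,26,,
Copper,2009-09-22,NH4-N,<0.01,,
Copper,2009-09-22,NO3-N,<0.001,,
Copper,2009-09-22,PO4-P,<0.001,,
Copper,2009-09-22,TN,0.070,,
Copper,2009-09-22,TP,0.004,,0.002
Copper,2009-09-22,Chl-a,0.54,,
Hidden NOCA,2009-09-24,spec_cond,5.6,,
Hidden NOCA,2009-09-24,pH,6.7,,
Hidden NOCA,2009-09-24,ANC,30,,
Hidden NOCA,2009-09-24,NH4-N,<0.01,,
Hidden NOCA,2009-09-24,NO3-N,0.001,,0.001
Hidden NOCA,2009-09-24,PO4-P,<0.001,,
Hidden NOCA,2009-09-24,TN,0.050,,
Hidden NOCA,2009-09-24,TP,0.002,,0.002
Hidden NOCA,2009-09-24,Chl-a,0.23,,
Lower Thornton,2009-09-23,spec_cond,10.3,,
Lower Thornton,2009-09-23,pH,6.9,,
Lower Thornton,2009-09-23,ANC,50,,
Lower Thornton,2009-09-23,NH4-N,<0.01,,
Lower Thornton,2009-09-23,NO3-N,0.004,,0.001
Lower Thornton,2009-09-23,PO4-P,<0.001,,
Lower Thornton,2009-09-23,TN,0.100,,
Lower Thornton,2009-09-23,TP,0.003,,0.002
Lower Thornton,2009-09-23,Chl-a,0.8,,
Stiletto,2009-08-26,spec_cond,9.4,,
Stiletto,2009-08-26,pH,6.3,,
Stiletto,2009-08-26,ANC,90,,
Stiletto,2009-08-26,NH4-N,<0.01,,
Stiletto,2009-08-26,NO3-N,0.006,,0.001
Stiletto,2009-08-26,PO4-P,0.003,,0.001
Stiletto,2009-08-26,TN,0.270,,
Stiletto,2009-08-26,TP,0.007,,0.002
Stiletto,2009-08-26,Chl-a,1.03,,
Heather,2009-09-10,spec_cond,71.0,,
Heather,2009-09-10,pH,7.2,,
Heather,2009-09-10,ANC,374,,
Heather,2009-09-10,NH4-N,<0.01,,
Heather,2009-09-10,NO3-N,0.007,,0.001
Heather,2009-09-10,PO4-P,0.001,,0.001
Heather,2009-09-10,TN,0.060,,
Heather,2009-09-10,TP,0.005,,0.002
Heather,2009-09-10,Chl-a,0.62,,
Hoh,2009-09-08,spec_cond,62.2,,
Hoh,2009-09-08,pH,7.5,,
Hoh,2009-09-08,ANC,394,,
Hoh,2009-09-08,NH4-N,<0.01,,
Hoh,2009-09-08,NO3-N,0.001,,0.001
Hoh,2009-09-08,PO4-P,<0.001,,
Hoh,2009-09-08,TN,0.160,,
Hoh,2009-09-08,TP,0.007,,0.002
Hoh,2009-09-08,Chl-a,0.63,,
Milk,2009-09-11,spec_cond,37.2,,
Milk,2009-09-11,pH,7.2,,
Milk,2009-09-11,ANC,284,,
Milk,2009-09-11,NH4-N,<0.01,,
Milk,2009-09-11,NO3-N,<0.001,,
Milk,2009-09-11,PO4-P,<0.001,,
Milk,2009-09-11,TN,0.040,,
Milk,2009-09-11,TP,0.004,,0.002
Milk,2009-09-11,Chl-a,0.28,,
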