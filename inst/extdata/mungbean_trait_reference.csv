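trait,name,unit,mean,sd,min,max,cv,iqr,skewness,kurtosis,gcv,pcv,h2,h2_category,ga,ga_category,gg,gg_category
TLL,Terminal leaf length,cm,8.5,1.1,5.0,12.7,13,1.47,0.11,0.2,5.98,13.17,20.62,Low,0.48,Low,5.60,Low
TLW,Terminal leaf width,cm,6.7,1.1,3.3,11,15.9,1.43,0.17,0.13,8.16,16.03,25.92,Low,0.58,Low,8.57,Low
PH,Plant height,cm,71.3,14.1,30.4,145.6,19.8,19.53,0.23,0.41,17.18,19.74,75.70,High,22.02,High,30.83,High
PTL,Petiole length,cm,9.7,1.9,3.4,18.1,19.3,2.4,0.31,0.37,11.62,19.35,36.05,Medium,1.40,Low,14.39,Medium
PDL,Peduncle length,cm,15.0,4.3,3.9,27.7,28.3,5.7,-0.07,-0.31,21.05,28.30,55.32,Medium,4.85,Low,32.30,High
PL,Pod length,cm,7.9,1.2,4.6,13.8,15.5,1.23,1.27,2.14,13.15,15.54,71.63,High,1.81,Low,22.96,High
NPPC,Number of pods per cluster,count,4.1,1.3,1.0,9.0,31.6,1.7,0.44,0.19,23.10,31.52,53.70,Medium,1.42,Low,34.92,High
SD,Stem diameter,mm,11.4,2.2,5.2,19.7,19.4,2.93,0.4,0.12,15.16,19.31,61.62,High,2.80,Low,24.55,High
NPB,Number of primary branches,count,4.0,1.1,1.0,9.0,29,1.37,0.27,0.23,20.42,28.97,49.68,Medium,1.18,Low,29.69,High
NSPP,Number of seeds per pod,count,12.0,1.0,6.3,16.3,8.5,1.33,-0.53,1.96,5.96,8.58,48.36,Medium,1.03,Low,8.56,Low
NPPP,Number of pods per plant,count,45.4,23.8,2.0,173.3,52.5,30.33,1.02,1.52,29.75,52.26,32.42,Medium,15.95,Medium,34.95,High
PB,Plant biomass,g,48.4,22,8.0,194,45.5,27.33,1.33,3.51,38.09,45.61,69.76,High,31.69,High,65.63,High
DFF,Days to 50 percent flowering,days,49.3,8.8,31.0,89,17.8,11,0.9,0.87,16.48,17.84,85.40,High,15.48,Medium,31.42,High
DM,Days to 80 percent maturity,days,79.9,7.6,59.0,110,9.6,9,0.15,0.1,7.53,9.55,62.10,High,9.76,Low,12.23,Medium
GY,Grain yield per plant,g,11.7,6.8,1.0,46.4,57.9,9.13,0.76,0.74,23.41,57.80,16.40,Low,2.29,Low,19.55,Medium
SW,100 seed weight,g,3.3,1.0,1.17,8.0,29.8,1.05,1.16,1.42,25.83,30.03,74.01,High,1.52,Low,45.85,High
SA,Seed area,mm2,15.9,3.0,5.9,28.1,19,3.17,1.01,1.19,16.66,18.97,77.14,High,4.79,Low,30.19,High
SL,Seed length,mm,5.1,0.5,3.1,7.2,9.9,0.56,0.86,1.12,8.65,9.93,75.80,High,0.79,Low,15.53,Medium
SB,Seed breadth,mm,4.0,0.4,2.5,5.4,9,0.43,0.5,0.52,7.28,8.98,65.74,High,0.49,Low,12.18,Medium
SR,Seed roundness,ratio,0.8,0.03,0.6,0.9,4.2,0.04,-0.09,0.29,2.30,4.19,30.03,Medium,0.02,Low,2.60,Low
PWPP,Pod weight per plant,g,18.9,10.3,1.0,73.3,54.5,13.34,0.8,0.9,21.08,54.55,14.93,Low,3.19,Low,16.80,Medium
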