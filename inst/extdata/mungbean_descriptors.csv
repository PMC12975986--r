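trait,kind,unit,states
TLL,quantitative,cm,
TLW,quantitative,cm,
PH,quantitative,cm,
PTL,quantitative,cm,
PDL,quantitative,cm,
PL,quantitative,cm,
NPPC,quantitative,count,
SD,quantitative,mm,
NPB,quantitative,count,
NSPP,quantitative,count,
NPPP,quantitative,count,
PB,quantitative,g,
DFF,quantitative,days,
DM,quantitative,days,
GY,quantitative,g,
SW,quantitative,g,
SA,quantitative,mm2,
SL,quantitative,mm,
SB,quantitative,mm,
SR,quantitative,ratio,
PWPP,quantitative,g,
HC,qualitative,,green|light green|greenish purple|purple|dark purple
SV,qualitative,,low|medium|high
GH,qualitative,,erect|semi-erect|spreading
RP,qualitative,,above canopy|intermediate|within canopy
PA,qualitative,,erect|pendant
PP,qualitative,,glabrous|sparse|medium|dense
SC,qualitative,,green|dark green|light green|yellow|greenish yellow|brown|dark brown|black|mottled
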