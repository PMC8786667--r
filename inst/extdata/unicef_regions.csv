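country,region
AFG,South Asia
AGO,Eastern and Southern Africa
ARG,Latin America and Caribbean
AUS,East Asia and Pacific
BGD,South Asia
BEN,West and Central Africa
BOL,Latin America and Caribbean
BRA,Latin America and Caribbean
BFA,West and Central Africa
BDI,Eastern and Southern Africa
KHM,East Asia and Pacific
CMR,West and Central Africa
CAN,North America
CAF,West and Central Africa
TCD,West and Central Africa
CHN,East Asia and Pacific
CIV,West and Central Africa
COL,Latin America and Caribbean
COD,West and Central Africa
COG,West and Central Africa
EGY,Middle East and North Africa
ETH,Eastern and Southern Africa
FRA,Europe and Central Asia
DEU,Europe and Central Asia
GHA,West and Central Africa
GIN,West and Central Africa
GNB,West and Central Africa
GNQ,West and Central Africa
HTI,Latin America and Caribbean
IND,South Asia
IDN,East Asia and Pacific
IRN,Middle East and North Africa
IRQ,Middle East and North Africa
ITA,Europe and Central Asia
JPN,East Asia and Pacific
KEN,Eastern and Southern Africa
LAO,East Asia and Pacific
LSO,Eastern and Southern Africa
LBR,West and Central Africa
MDG,Eastern and Southern Africa
MWI,Eastern and Southern Africa
MLI,West and Central Africa
MRT,West and Central Africa
MEX,Latin America and Caribbean
MOZ,Eastern and Southern Africa
MMR,East Asia and Pacific
NPL,South Asia
NER,West and Central Africa
NGA,West and Central Africa
PAK,South Asia
PNG,East Asia and Pacific
PER,Latin America and Caribbean
PHL,East Asia and Pacific
RUS,Europe and Central Asia
RWA,Eastern and Southern Africa
SEN,West and Central Africa
SLE,West and Central Africa
SOM,Eastern and Southern Africa
ZAF,Eastern and Southern Africa
SSD,Eastern and Southern Africa
ESP,Europe and Central Asia
SDN,Middle East and North Africa
TZA,Eastern and Southern Africa
THA,East Asia and Pacific
TGO,West and Central Africa
TUR,Europe and Central Asia
UGA,Eastern and Southern Africa
GBR,Europe and Central Asia
USA,North America
VEN,Latin America and Caribbean
VNM,East Asia and Pacific
YEM,Middle East and North Africa
ZMB,Eastern and Southern Africa
ZWE,Eastern and Southern Africa
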