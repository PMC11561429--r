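code,name,aliases
US,United States,USA|America|United States of America
GB,United Kingdom,UK|Britain|Great Britain
FR,France,
DE,Germany,
IT,Italy,
ES,Spain,
PT,Portugal,
NL,Netherlands,Holland
BE,Belgium,
CH,Switzerland,
AT,Austria,
SE,Sweden,
NO,Norway,
DK,Denmark,
FI,Finland,
IE,Ireland,
PL,Poland,
CZ,Czechia,Czech Republic
GR,Greece,
TR,Turkey,Turkiye
RU,Russia,Russian Federation
UA,Ukraine,
CN,China,
JP,Japan,
KR,South Korea,Republic of Korea
IN,India,
PK,Pakistan,
BD,Bangladesh,
ID,Indonesia,
PH,Philippines,
TH,Thailand,
VN,Vietnam,Viet Nam
MY,Malaysia,
SG,Singapore,
AU,Australia,
NZ,New Zealand,
CA,Canada,
MX,Mexico,
BR,Brazil,
AR,Argentina,
CL,Chile,
CO,Colombia,
PE,Peru,
ZA,South Africa,
NG,Nigeria,
KE,Kenya,
UG,Uganda,
TZ,Tanzania,
ET,Ethiopia,
GH,Ghana,
EG,Egypt,
MA,Morocco,
SA,Saudi Arabia,
AE,United Arab Emirates,UAE
IL,Israel,
IR,Iran,
IQ,Iraq,
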