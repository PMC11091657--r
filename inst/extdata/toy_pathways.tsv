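reaction_id	pathway
GLCpts	glycolysis
PGI	glycolysis
PFK	glycolysis
FBA	glycolysis
TPI	glycolysis
GAPD	glycolysis
PGK	glycolysis
PGM	glycolysis
ENO	glycolysis
PYK	glycolysis
PDH	glycolysis
G6PDHL	pentose phosphate pathway
GND	pentose phosphate pathway
RPI	pentose phosphate pathway
RPE	pentose phosphate pathway
TKT1	pentose phosphate pathway
TALA	pentose phosphate pathway
TKT2	pentose phosphate pathway
PPC	TCA cycle
CS	TCA cycle
ACONT	TCA cycle
ICDHyr	TCA cycle
AKGDH	TCA cycle
SUCOAS	TCA cycle
SUCDi	TCA cycle
FUM	TCA cycle
MDH	TCA cycle
ME2	TCA cycle
PTAr	acetate fermentation
ACKr	acetate fermentation
ACt2r	acetate fermentation
GLUDy	GABA shunt
GLUDC	GABA shunt
ABTA	GABA shunt
SSALy	GABA shunt
GABAt	GABA shunt
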