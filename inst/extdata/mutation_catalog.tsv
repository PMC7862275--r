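id	gene	transcript	variant	protein_change
TET2a	TET2	NM_001127208	c.3743T>C	p.Leu1248Pro
JAK2	JAK2	NM_004972	c.1849G>T	p.Val617Phe
TET2b	TET2	NM_017628	c.3409_3416delGGTAATGT	p.Gly1137Profs*5
ASXL1	ASXL1	NM_015338	c.1934dupG	p.Gly646Trpfs*12
SRSF2	SRSF2	NM_003016	c.284C>A	p.Pro95His
TP53	TP53	NM_000546	c.713G>C	p.Cys238Ser
FLT3	FLT3	NM_004119	c.2503G>C	p.Asp835Tyr
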