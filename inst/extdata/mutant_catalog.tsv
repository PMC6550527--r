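phage	subcluster	inheritance	lys_recovery	parent	mutant_type	mutations	l5_clade
Bxb1	A1	int	Yes	NA	NA	NA	FALSE
Dreamboat	A1	int	Yes	NA	NA	NA	FALSE
Petruchio	A1	int	Yes	NA	NA	NA	FALSE
MissWhite	A2	int	No	?	NA	(Δrep)	TRUE
D29	A2	int	NA	?	NA	(rep Δ5' end)	TRUE
Echild	A2	parABS	No	NA	NA	NA	TRUE
Journey13	A2	int	No	NA	NA	NA	TRUE
Piro94	A2	int	No	NA	NA	NA	TRUE
ArcherNM	A2	parABS	Yes	NA	NA	NA	TRUE
Drake55	A2	int	Yes	NA	NA	NA	TRUE
Jaan	A2	int	Yes	NA	NA	NA	TRUE
L5	A2	int	Yes	NA	NA	NA	TRUE
LadyBird	A2	parABS	Yes	NA	NA	NA	TRUE
Larenn	A2	int	Yes	NA	NA	NA	TRUE
RedRock	A2	parABS	Yes	NA	NA	NA	TRUE
Serenity	A2	int	Yes	NA	NA	NA	TRUE
StarStuff	A2	int	Yes	NA	NA	NA	TRUE
Trixie	A2	int	Yes	NA	NA	NA	TRUE
Updawg	A2	int	Yes	NA	NA	NA	TRUE
Peaches	A4	int	NA	NA	NA	NA	FALSE
Jeffabunny	A6	parABS	No	?	NA	(Δrep)	TRUE
DaVinci	A6	parABS	Yes	NA	NA	NA	TRUE
Gladiator	A6	parABS	Yes	NA	NA	NA	TRUE
Alma	A9	parABS	Yes	NA	NA	NA	TRUE
Pioneer	A9	parABS	Yes	NA	NA	NA	TRUE
Et2Brutus	A11	parABS	Yes	NA	NA	NA	TRUE
Mulciber	A11	parABS	Yes	NA	NA	NA	TRUE
DarthPhader	A12	int	Yes	NA	NA	NA	TRUE
EagleEye	A16	parABS	Yes	NA	NA	NA	TRUE
phiTM45	A1	int	NA	Bxb1	Bxb1 CRS DEM	G44351A (Rep Q138*)	FALSE
phiTM1	A2	int	Yes	L5	BRED	44333:44334 27-bp ins (Rep-HA)	TRUE
phiTM4	A2	int	No	phiTM1	Unintentional isolate	G43843T (gp70 A145E)	TRUE
phiTM6	A2	int	Yes	L5	BRED	44333:44334 24-bp ins (Rep-FLAG)	TRUE
phiTM33	A2	int	No	Che12	Unintentional isolate	Δ44705:47517 (rep Δ5' end); C18749A (gp29 F223L)	TRUE
phiTM41	A2	int	Yes	L5	Trixie Lys DEM	G50942T (gp89 F47L)	TRUE
phiTM42	A2	int	NA	Trixie/RedRock	Trixie Lys DEM	rec Tx 44620:44630 and RR 44127:44137; rec Tx 53508:53524 and RR 53314:53330; RR Δ47296:51394; RR 45315:45316 G insertion (Rep R149fs)	TRUE
phiTM43	A2	int	No	D29	Unintentional isolate	C25024T (gp32 P202S)	TRUE
phiTM44	A2	int	No	D29	Unintentional isolate	C25024A (gp32 P202T); C40378T (gp59.2 sense)	TRUE
phiTM38	A2	int	NA	phiTM44	Et2Brutus Lys DEM	C45518A (rep pm)	TRUE
phiTM46	A6	parABS	NA	DaVinci	Gladiator CRS DEM	43427:43428 G insertion (Rep R52fs)	TRUE
phiTM47	A6	parABS	NA	Gladiator	Gladiator CRS DEM	43878:43879 G insertion (Rep G135fs)	TRUE
phiTM35	A9	parABS	NA	Pioneer	EagleEye Lys DEM	G44573T (Rep Y48*); Δ3425:5091	TRUE
phiTM39	A11	parABS	NA	Et2Brutus	L5 Lys DEM	G44580T (Rep S102*); T7649G (Holin V9G); G50548T (gp98 sense)	TRUE
phiTM40	A11	parABS	NA	Et2Brutus	Trixie Lys DEM	G44772A (Rep A38V); T7667G (Holin I15S)	TRUE
phiTM36	A16	parABS	NA	EagleEye	Pioneer Lys DEM	Δ45310:48001 (Δrep)	TRUE
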