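protein	ko	hmm	gene	pathway
polysaccharide export outer membrane protein Wza	K01991	PF02563	wza	EPS
alginate export outer membrane protein AlgE	K16081	PF13372	algE	EPS
alginate biosynthesis acetyltransferase AlgJ	K19295	PF16822	algJ	EPS
colanic acid biosynthesis acetyltransferase WcaB	K03819	TIGR04016	wcaB	EPS
colanic acid biosynthesis acetyltransferase WcaF	K03818	TIGR04008	wcaF	EPS
colanic acid/amylovoran biosynthesis pyruvyl transferase WcaK/AmsJ	K16710	TIGR04006	wcaK/amsJ	EPS
capsular polysaccharide export system permease KpsE	K10107	TIGR01010	kpsE	EPS
exopolysaccharide biosynthesis transmembrane protein EpsG	K19419	PF14897	epsG	EPS
exopolysaccharide biosynthesis tyrosine kinase modulator EpsA	K19420	TIGR01006	epsA	EPS
levansucrase SacB	K00692	PF02435	sacB	EPS
lipopolysaccharide transport system ATP-binding protein Wzt	K09691	PF14524	wzt	LPS
LptBFGC lipopolysaccharide export complex permease LptF	K07091	TIGR04407	lptF	LPS
LptBFGC lipopolysaccharide export complex permease LptG	K11720	TIGR04408,PF03739	lptG	LPS
LptBFGC lipopolysaccharide export complex inner membrane protein LptC	K11719	TIGR04409,PF06835	lptC	LPS
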