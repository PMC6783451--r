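scaffold	pos	ref	alt	f_hom_ref	f_het	f_hom_alt	m_hom_ref	m_het	m_hom_alt	p_printed
scaffold_064	3723782	A	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3723876	A	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3723925	T	C	16	0	0	0	15	0	3.33e-09
scaffold_064	3724050	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3724051	A	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3724070	A	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3724479	G	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3724481	T	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3724494	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3724556	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3724561	C	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3724625	T	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3724697	GTAATGTAG	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3725864	T	C	16	0	0	0	15	0	3.33e-09
scaffold_064	3725869	G	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3725870	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3725892	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3725903	G	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3725915	G	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3725924	G	C	16	0	0	0	15	0	3.33e-09
scaffold_064	3725968	G	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3725974	G	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3726082	A	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3726098	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726136	G	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726155	A	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3726182	G	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726338	G	C	16	0	0	0	15	0	3.33e-09
scaffold_064	3726374	T	C	16	0	0	0	15	0	3.33e-09
scaffold_064	3726420	G	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3726427	A	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726477	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726480	T	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3726530	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726649	G	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726723	T	A	16	0	0	0	14	0	6.88e-09
scaffold_064	3726751	A	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3726760	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3726826	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3727016	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3727037	A	G	16	0	0	0	15	0	3.33e-09
scaffold_064	3727050	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3727069	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3729537	C	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3729736	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3729866	T	C	16	0	0	0	15	0	3.33e-09
scaffold_064	3730062	C	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3730221	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3730222	G	A	16	0	0	0	15	0	3.33e-09
scaffold_064	3730268	C	T	16	0	0	0	15	0	3.33e-09
scaffold_064	3730295	T	A	16	0	0	0	15	0	3.33e-09
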