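name	sequence
LL-miR01	uaguaaguuugcagagcagag
LL-miR02	cuugugcuucuggacugcucc
LL-miR03	aagguauagagucagacacuu
LL-miR04	agacgaucgcaccaaacuggcuau
LL-miR05	uuuucuaugucacucaauccaa
LL-miR06	aguaaguugagaagaguaggagaa
LL-miR07	uucacugccaccauccgccugu
LL-miR08	cgguugcuuagcuuguacucu
LL-miR09	ugcaccuccuccuccuuuucu
LL-miR10	gguuugaugaaucugagcauc
LL-miR11	uuacgugucccuuaaucugacggg
LL-miR12	gcucggguuaacggggaagug
LL-miR13	uaugaaguuauauagguuguccgg
LL-miR14	uuuacugccaccauccgccugc
LL-miR15	aagguaagagaaucaacaagaggu
LL-miR16	uaggcaacaaauuagagucucu
LL-miR17	uuuguauggucuguugaaauu
LL-miR18	caggcggcgaggauggggaug
LL-miR19	uugcuuagcuuguacucucgc
LL-miR20	ugaaaauguagcacuagcacc
LL-miR21	uugagaguagagagccaggug
LL-miR22	aaaugaugaaucugagccuc
LL-miR23	uagaggcgaugaugaugaaau
LL-miR24	ugaagacuuggcaaccgacauc
LL-miR25	ucugcccugauaugagcuccag
LL-miR26	ucugaauagcaaacccaauuc
LL-miR27	aaacgaucgauaaaccucugc
LL-miR28	aaugagaagacuagugacaagauu
LL-miR29	uucccuucggcugcaaauagc
LL-miR30	uagaggcgaugaugaugaaau
LL-miR31	aucuuuggccuggagauagagg
LL-miR32	ugugccaugcugugugcgucc
LL-miR33	ugccgggcuaagauacaaggau
LL-miR34	ucuauaugacucucggcaacgg
LL-miR35	uccaaagucagugaggggagc
LL-miR36	uucgagugacauauggaaacu
LL-miR37	ucaaucuuuggccuggagauagag
LL-miR38	ugggucuccucucauuccaug
LL-miR39	uucgagugacauauggaaacu
LL-miR40	ucaaagacgaaucugagcaua
LL-miR41	ucguaucugugguuugcuccu
LL-miR42	ugcaguuugguuuguggugug
LL-miR43	cugucgagcuuccauacuggc
LL-miR44	uggaucuugaaccaaguguuc
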