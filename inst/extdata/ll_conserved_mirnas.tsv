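family	name	sequence
MIR156	LL-miR156a	ugacagaagagagugagcac
MIR156	LL-miR156i	ugacagaaagaguagugagca
MIR159	LL-miR159a	uggauugaagggagcucuaca
MIR159	LL-miR159b	uuuggauugaagggagcucua
MIR159	LL-miR319a	uuggacugaagggagcucccu
MIR160	LL-miR160a	ugccuggcucccuguaugcca
MIR160	LL-miR160f	cugccuggcucccugaaugcc
MIR162	LL-miR162a	ucgauaaaccucugcauccgg
MIR164	LL-miR164a	uggagaagcagggcacgugca
MIR166	LL-miR166f	ucucggaccaggcuucauucc
MIR166	LL-miR166g	ucggaccaggcuucauuccuc
MIR167	LL-miR167a	ugaagcugccagcaugaucuga
MIR168	LL-miR168a	ucgcuuggugcaggucgggaa
MIR172	LL-miR172a	agaaucuugaugaugcugcaa
MIR390	LL-miR390a	aagcucaggagggauagcgcc
MIR395	LL-miR395a	ugaaguguuugggggaacucc
MIR395	LL-miR395k	ugaagcguuugggggaacucc
MIR396	LL-miR396a	uuccacagcuuucuugaacug
MIR396	LL-miR396f	uuccacggcuuucuugaacua
MIR398	LL-miR398b	uguguucucaggucaccccug
MIR399	LL-miR399a	ugccaaaggagacuugcccug
MIR408	LL-miR408b	ugcacugccucuucccuggcu
MIR845	LL-miR845	cgcucugauaccacuuguugg
MIR2118	LL-miR2118e	uucccaaugccucucaugccaa
MIR2118	LL-miR2118a	uugccgauaccacccauaccga
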