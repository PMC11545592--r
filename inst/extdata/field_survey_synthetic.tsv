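group	genus	species	count
fish	Zacco	Zacco temminckii	141
fish	Zacco	Zacco koreanus	38
fish	Rhinogobius	Rhinogobius brunneus	62
fish	Misgurnus	Misgurnus anguillicaudatus	9
fish	Carassius	Carassius auratus	14
fish	Odontobutis	Odontobutis obscurus	55
fish	Pseudogobio	Pseudogobio esocinus	21
fish	Squalidus	Squalidus gracilis	17
fish	Pungtungia	Pungtungia herzi	12
fish	Oryzias	Oryzias latipes	26
fish	Anguilla	Anguilla japonica	3
fish	Tridentiger	Tridentiger brevispinis	8
benthic_invertebrate	Chironomus	NA	88
benthic_invertebrate	Polypedilum	NA	74
benthic_invertebrate	Ephemera	NA	41
benthic_invertebrate	Radix	NA	23
benthic_invertebrate	Baetis	NA	96
benthic_invertebrate	Ecdyonurus	NA	34
benthic_invertebrate	Epeorus	NA	18
benthic_invertebrate	Caenis	NA	27
benthic_invertebrate	Cheumatopsyche	NA	52
benthic_invertebrate	Hydropsyche	NA	44
benthic_invertebrate	Rhyacophila	NA	11
benthic_invertebrate	Stenopsyche	NA	16
benthic_invertebrate	Gammarus	NA	63
benthic_invertebrate	Asellus	NA	9
benthic_invertebrate	Caridina	NA	31
benthic_invertebrate	Macrobrachium	NA	7
benthic_invertebrate	Semisulcospira	NA	48
benthic_invertebrate	Physa	NA	13
benthic_invertebrate	Cipangopaludina	NA	5
benthic_invertebrate	Erpobdella	NA	6
benthic_invertebrate	Tubifex	NA	19
benthic_invertebrate	Orthetrum	NA	8
benthic_invertebrate	Calopteryx	NA	10
benthic_invertebrate	Sialis	NA	4
benthic_invertebrate	Tipula	NA	12
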