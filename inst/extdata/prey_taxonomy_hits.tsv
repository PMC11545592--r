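otu_id	taxon	percent_identity	query_coverage_pct	max_score	accession
OTU_001	Micropterus salmoides	100.0	100	579	MT455106.1
OTU_002	Misgurnus anguillicaudatus	100.0	100	579	MF122502.1
OTU_003	Carassius cuvieri	100.0	100	579	MT571744.1
OTU_004	Zacco sp. 1	98.7	100	556	MT457508.1
OTU_005	Zacco sp. 2	100.0	100	579	MT457518.1
OTU_006	Rhinogobius brunneus	100.0	100	579	OL674307.1
OTU_007	Hemibarbus labeo	99.7	100	573	OL674364.1
OTU_008	Chironomus flaviplumus	97.4	100	534	MN521255.1
OTU_009	Cricotopus triannulatus	100.0	100	579	LC050962.1
OTU_010	Polypedilum japonicum	99.7	100	573	LC329191.1
OTU_011	Polypedilum yongsanensis	100.0	100	579	NC_072650.1
OTU_012	Ephemera orientalis	99.0	100	562	OL664518.1
OTU_013	Platycnemis phyllopoda	99.7	100	573	KF257109.1
OTU_014	Radix sp.	99.0	100	564	LC658589.1
OTU_015	Limnodrilus sp.	100.0	100	579	KY369698.1
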