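gene_id	symbol	effect	note
AT5G53210	SPCH	-1	loss abolishes stomatal lineage entry; synthetic curated stand-in list
AT3G06120	MUTE	-1	loss blocks meristemoid-to-GMC transition
AT3G24140	FAMA	-1	loss prevents guard cell differentiation
AT3G26744	ICE1	-1	scrm loss reduces stomatal density
AT1G12860	SCRM2	-1	loss reduces stomatal density (redundant with ICE1)
AT4G12970	EPFL9	-1	STOMAGEN loss decreases density
AT1G05230	HDG2	-1	loss impairs stomatal differentiation
AT3G54180	CDKB1;1	-1	dominant-negative reduces stomatal index
AT5G02110	CYCD7;1	-1	loss slows GMC division, fewer stomata
AT4G31805	POLAR	-1	loss reduces amplifying divisions
AT2G20875	EPF1	1	loss increases stomatal density
AT1G34245	EPF2	1	loss increases density and arrested precursors
AT1G80080	TMM	1	loss causes clustered stomata, higher density
AT1G04110	SDD1	1	loss increases density two- to fourfold
AT2G26330	ER	1	erecta loss increases stomatal density
AT5G62230	ERL1	1	loss increases density (ERECTA family)
AT5G07180	ERL2	1	loss increases density (ERECTA family)
AT1G63700	YDA	1	MAPKKK loss gives stomatal clusters
AT3G45640	MPK3	1	MAPK pathway loss increases stomatal production
AT2G43790	MPK6	1	MAPK pathway loss increases stomatal production
AT1G51660	MKK4	1	MAPKK loss increases stomatal production
AT3G21220	MKK5	1	MAPKK loss increases stomatal production
AT1G14350	FLP	1	loss gives paired/clustered stomata
AT2G02820	MYB88	1	loss (with FLP) increases stomatal clusters
AT5G60880	BASL	0	polarity gene; density effect context dependent
AT1G69320	CLE10	0	peptide ligand; no confirmed density effect
AT1G33240	GTL1	0	trichome/ploidy regulator; density effect unconfirmed
AT4G21750	ATML1	0	epidermal identity; no direct density phenotype
AT4G04890	PDF2	0	epidermal identity; no direct density phenotype
AT3G48750	CDKA;1	0	core cell cycle; pleiotropic
AT2G30370	EPFL6	0	CHALLAH; acts outside leaf epidermis
AT4G14723	EPFL4	0	stem-expressed EPF-like
AT4G37810	EPFL2	0	margin-expressed EPF-like
AT4G33430	BAK1	0	co-receptor; pleiotropic
AT1G71830	SERK1	0	co-receptor; pleiotropic
AT1G34210	SERK2	0	co-receptor; pleiotropic
AT3G57230	AGL16	0	miR824 target; density effect unconfirmed
AT5G65590	SCAP1	0	guard cell maturation, not density
AT1G73360	HDG11	0	HD-ZIP IV; density effect unconfirmed
AT2G26300	GPA1	0	G-protein signalling; pleiotropic
AT5G28640	AN3	0	GIF1 coactivator; pleiotropic
AT4G18710	BIN2	0	GSK3 kinase; pleiotropic
AT1G08810	MYB60	0	guard cell aperture, not density
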