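taxon	domain	category	v3_length_bp	homd_abundance_pct
Actinomyces naeslundii	Bacteria	oral_commensal	190	0.23
Anaerolineae G-1 sp.	Bacteria	oral_commensal	169	NA
Atopobium parvulum	Bacteria	oral_commensal	173	0.30
Campylobacter gracilis	Bacteria	oral_commensal	169	1.04
Corynebacterium matruchotii	Bacteria	oral_commensal	189	0.49
Eubacterium saphenum	Bacteria	oral_commensal	171	0.37
Fusobacterium nucleatum	Bacteria	oral_commensal	172	1.35
Methanobrevibacter oralis	Archaea	oral_commensal	151	NA
Mogibacterium timidum	Bacteria	oral_commensal	171	0.27
Neisseria mucosa	Bacteria	oral_commensal	193	0.33
Oribacterium sinus	Bacteria	oral_commensal	168	0.14
Parvimonas micra	Bacteria	oral_commensal	168	0.68
Prevotella melaninogenica	Bacteria	oral_commensal	188	0.22
Rothia dentocariosa	Bacteria	oral_commensal	173	0.60
Streptococcus mitis	Bacteria	oral_commensal	194	5.66
TM7 spp.	Bacteria	oral_commensal	168	0.24
Veillonella parvula	Bacteria	oral_commensal	194	6.63
Lactobacillus salivarius	Bacteria	caries_pathogen	193	0.09
Streptococcus mutans	Bacteria	caries_pathogen	194	4.31
Aggregatibacter actinomycetemcomitans	Bacteria	periodontal_pathogen	193	0.03
Filifactor alocis	Bacteria	periodontal_pathogen	171	0.31
Porphyromonas gingivalis	Bacteria	periodontal_pathogen	188	0.26
Tannerella forsythia	Bacteria	periodontal_pathogen	188	0.25
Treponema denticola	Bacteria	periodontal_pathogen	194	0.22
Bordetella pertussis	Bacteria	respiratory_pathogen	193	NA
Corynebacterium diphtheriae	Bacteria	respiratory_pathogen	173	NA
Haemophilus influenzae	Bacteria	respiratory_pathogen	193	0.29
Streptococcus pneumoniae	Bacteria	respiratory_pathogen	194	0.18
Streptococcus pyogenes	Bacteria	respiratory_pathogen	194	NA
Neisseria meningitidis	Bacteria	systemic_pathogen	193	0.17
Mycobacterium tuberculosis	Bacteria	systemic_pathogen	185	NA
Mycobacterium leprae	Bacteria	systemic_pathogen	185	NA
Treponema pallidum	Bacteria	systemic_pathogen	194	NA
Streptophyta (plant chloroplast)	Chloroplast	dietary	170	NA
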