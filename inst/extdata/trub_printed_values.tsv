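# Published scalar values for Triatoma rubrofasciata used as inputs by the
# acceptance report: read accounting, the GATA-variant monomer behind the
# TrubSat002-9 name, and the printed per-sample abundances of the two most
# abundant satDNA families.
key	value
analysed_bases	271000000
genome_size_bases	1187000000
gata_variant_monomer	GATAGATTA
TrubSat002-9_male_percent	3.77
TrubSat002-9_female_percent	0.02
TrubSat001-166_male_percent	20.43
TrubSat001-166_female_percent	5.48
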