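# Published RepeatExplorer2 genome-composition estimates for Triatoma
# rubrofasciata (male, Vietnam; female, China), transcribed from the study's
# printed table. Values are genome proportions in percent.
sample	non_repetitive	LTR	non_LTR	classII	satDNA	rDNA	unclassified
Vietnam_male	74.74	0.02	1.62	0.87	17.68	0.14	4.92
China_female	83.8	0.02	2.63	1.02	7.07	0.47	4.98
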