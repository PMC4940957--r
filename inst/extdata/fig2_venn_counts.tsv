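# Three-genotype detection Venn regions for identified lncRNAs, transcribed
# from the source study's diagrams: the full 7-region partition for all
# lncRNAs, and the regions the text states for the genome-hit and
# no-genome-hit subsets (all_three and wild_f1, plus subset totals). Region
# codes: dom/wild/f1 presence.
diagram	region	count
all	all_three	18569
all	dom_f1	3062
all	wild_f1	3377
all	f1_only	317
all	dom_only	2
all	wild_only	0
all	dom_wild	0
genome_hit	total	23960
genome_hit	all_three	18128
genome_hit	wild_f1	2644
no_genome_hit	total	1367
no_genome_hit	all_three	441
no_genome_hit	wild_f1	733
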