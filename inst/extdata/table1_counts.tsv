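# lncRNA feature summary: count cells transcribed from the source study's
# printed feature table (three strata x five feature rows + totals; not-DE /
# DE / total counts per row). Percentages are never stored — the report
# module recomputes them from these counts with the caption rule.
# Strata: all = every identified lncRNA; meiocyte_exclusive = detected in
# meiocytes only; shared = detected in both transcriptomes (exclusive ones
# excluded). Counts are additive: all = meiocyte_exclusive + shared, cell by
# cell.
stratum	feature	not_de	de	total
all	genome_hit	8925	9024	17949
all	three_genotypes	8250	7421	15671
all	three_genotypes_and_genome_hit	8083	7227	15310
all	srna_similarity	3035	3800	6835
all	contains_te	831	928	1759
all	total	12006	13321	25327
meiocyte_exclusive	genome_hit	2605	3406	6011
meiocyte_exclusive	three_genotypes	1564	1334	2898
meiocyte_exclusive	three_genotypes_and_genome_hit	1520	1298	2818
meiocyte_exclusive	srna_similarity	1081	1454	2535
meiocyte_exclusive	contains_te	279	288	567
meiocyte_exclusive	total	2881	4014	6895
shared	genome_hit	6320	5618	11938
shared	three_genotypes	6686	6087	12773
shared	three_genotypes_and_genome_hit	6563	5929	12492
shared	srna_similarity	1954	2346	4300
shared	contains_te	552	640	1192
shared	total	9125	9307	18432
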