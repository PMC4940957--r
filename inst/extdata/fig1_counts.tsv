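# Coding-class breakdown of differentially expressed genes (DEGs between the
# domesticated and wild genotypes at FDR 1 %): counts transcribed from the
# source study. total_genes is the collapsed-gene dataset size as given in
# the running text; total_genes_caption is the slightly different figure
# printed in the figure caption (a source-internal inconsistency, kept as
# data). noncoding_deg = lncRNA_deg + unclassified_deg.
quantity	count
total_genes	59085
total_genes_caption	59058
deg	29469
coding_deg	10702
noncoding_deg	18767
lncRNA_deg	13321
unclassified_deg	5446
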