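#!/usr/bin/env Rscript
# Step 5 — repetitive elements: TE annotation of the called lncRNAs against
# the family-coded library and trans-NAT flags against the NAT database,
# both at bit >= 70 and E <= 1e-6, with the family summary and the
# DNA/retrotransposon split.

source("analysis/00_config.R")

transcripts <- readDNAStringSet(file.path(DATA, "transcripts.fa"))
te_library <- readDNAStringSet(file.path(DATA, "te_library.fa"))
nat_db <- readDNAStringSet(file.path(DATA, "nat_db.fa"))
classes <- read_tsv("gene_classes.tsv")
truth_te <- read_tsv("data/truth_te.tsv")

lnc <- transcripts[classes$gene_id[classes$coding_class == "lncRNA"]]
message(sprintf("annotating %d lncRNAs against %d library elements ...",
                length(lnc), length(te_library)))
te <- annotate_te(lnc, te_library)
write_tsv(te$annotation, "te_annotation.tsv")
write_tsv(te$all_hits, "te_all_hits.tsv")

fs <- family_summary(te$annotation)
write_tsv(fs$by_family, "te_by_family.tsv")
write_tsv(fs$split, "te_split.tsv")
hit <- !is.na(te$annotation$te_family)
message(sprintf("lncRNAs with TE: %d (%.2f %%); split: %s",
                sum(hit), 100 * mean(hit),
                paste(fs$split$te_class, fs$split$percent, collapse = ", ")))
planted <- merge(truth_te, te$annotation, by.x = "id", by.y = "lncRNA_id")
if (nrow(planted) > 0) {
  message(sprintf("planted family recovery: %.1f %% of %d",
                  100 * mean(!is.na(planted$te_family) &
                               planted$te_family == planted$family),
                  nrow(planted)))
}

nat <- annotate_nat(lnc, nat_db)
write_tsv(nat, "nat_annotation.tsv")
message(sprintf("trans-NAT lncRNAs: %d (%.2f %%)",
                sum(nat$nat_flag), 100 * mean(nat$nat_flag)))
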