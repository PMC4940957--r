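#!/usr/bin/env Rscript
# Step 4 — small-RNA populations: length filtering, unique/redundant
# profiles, 5'-nucleotide bias of the 24-nt class, best-stratum mapping to
# the mixed reference (genome scaffolds + transcripts), association with
# gene classes, and miRNA family assignment against a family FASTA built
# from the planted precursors.

source("analysis/00_config.R")

reads <- read_tsv("data/srna_reads.tsv")
transcripts <- readDNAStringSet(file.path(DATA, "transcripts.fa"))
genome <- readDNAStringSet(file.path(DATA, "genome.fa"))
classes <- read_tsv("gene_classes.tsv")

fr <- filter_reads(reads)
message(sprintf("kept %d unique sequences (%d reads); dropped %d reads",
                nrow(fr$reads), sum(fr$reads$mult), sum(fr$dropped$mult)))

prof <- redundancy_profile(fr$reads)
write_tsv(prof, "srna_redundancy.tsv")
b24 <- five_prime_bias(fr$reads, 24)
write_tsv(data.frame(base = names(b24), fraction = round(unname(b24), 4)),
          "srna_5prime_24nt.tsv")
message(sprintf("24-nt 5' composition: A %.2f, C %.2f, G %.2f, T %.2f",
                b24["A"], b24["C"], b24["G"], b24["T"]))

message("best-stratum mapping to the mixed reference ...")
# map a capped subsample to keep the scan affordable at desk scale
set.seed(STUDY_SEED + 3L)
sub <- fr$reads[sample.int(nrow(fr$reads), min(600L, nrow(fr$reads))), ]
reference <- c(genome, transcripts)
kinds <- c(rep("genome", length(genome)), rep("transcript", length(transcripts)))
mp <- map_srna(sub, reference, kinds)
write_tsv(mp, "srna_mapping.tsv")

assoc <- associate_srna(mp, classes[, c("gene_id", "coding_class")])
write_tsv(assoc$gene_support, "srna_gene_support.tsv")
write_tsv(assoc$strand_by_class, "srna_strand_by_class.tsv")
write_tsv(data.frame(gene_id = names(assoc$srna_flag),
                     srna_similarity = unname(assoc$srna_flag)),
          "srna_flags.tsv")
by_class <- table(classes$coding_class[match(names(assoc$srna_flag)[assoc$srna_flag],
                                             classes$gene_id)])
message(sprintf("genes with sRNA similarity: %d (%s)",
                sum(assoc$srna_flag),
                paste(names(by_class), by_class, collapse = ", ")))

# miRNA-like family assignment: representatives are the most redundant
# 21-nt sequences (stand-ins for a curated family FASTA)
top21 <- fr$reads[fr$reads$length == 21, ]
top21 <- head(top21[order(-top21$mult), ], 5)
if (nrow(top21) > 0) {
  fams <- DNAStringSet(setNames(top21$seq, sprintf("fam%02d_1", seq_len(nrow(top21)))))
  fa <- mirna_family_assign(fr$reads[fr$reads$length <= 22, ], fams)
  write_tsv(fa$counts, "mirna_families.tsv")
  message(sprintf("reads assigned to %d families", nrow(fa$counts)))
}
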