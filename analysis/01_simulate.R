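#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs: transcripts (with ground
# truth), ordered peptide databases, the genome draft, meiocyte and somatic
# count matrices, small-RNA reads, and the TE library / NAT database with
# planted insertions and partners.

source("analysis/00_config.R")

message("generating transcripts ...")
g <- gen_transcripts(cfg_study)
truth <- g$truth

message("planting TE insertions and NAT partners ...")
nc_ids <- truth$id[truth$true_class == "noncoding"]
tn <- gen_te_nat(g$transcripts, cfg_study, noncoding_ids = nc_ids,
                 n_te = 50L, te_identity = 0.85, n_nat = 15L)
transcripts <- tn$transcripts  # TE copies now embedded

message("building the genome draft and peptide databases ...")
gg <- gen_genome(transcripts, cfg_study)
dbs <- gen_peptide_dbs(transcripts, truth, cfg_study)

message("simulating count matrices ...")
counts_mei <- gen_counts(truth$id, cfg_study, tissue = "meiocyte",
                         stage = "counts_meiocyte")
# somatic transcriptome: an independent draw in which a planted subset of
# (mostly noncoding) genes is silent, creating meiocyte-exclusive expression
counts_som <- gen_counts(truth$id, cfg_study, tissue = "somatic",
                         stage = "counts_somatic")
set.seed(STUDY_SEED + 2L)
silent_in_soma <- c(sample(nc_ids, round(0.4 * length(nc_ids))),
                    sample(truth$id[truth$true_class == "coding"], 10L))
counts_som$counts[silent_in_soma, ] <- 0L

message("simulating small-RNA populations ...")
sr <- gen_srna_reads(transcripts, cfg_study, n_reads = 5000L)

writeXStringSet(transcripts, file.path(DATA, "transcripts.fa"))
writeXStringSet(gg$genome, file.path(DATA, "genome.fa"))
writeXStringSet(tn$te_library, file.path(DATA, "te_library.fa"))
writeXStringSet(tn$nat_db, file.path(DATA, "nat_db.fa"))
for (nm in names(dbs)) {
  writeXStringSet(dbs[[nm]], file.path(DATA, paste0("peptides_", nm, ".fa")))
}
write_tsv(truth, "data/truth_transcripts.tsv")
write_tsv(tn$truth_te, "data/truth_te.tsv")
write_tsv(tn$truth_nat, "data/truth_nat.tsv")
write_tsv(gg$placement, "data/genome_placement.tsv")
write_tsv(cbind(gene_id = rownames(counts_mei$counts), counts_mei$counts),
          "data/counts_meiocyte.tsv")
write_tsv(counts_mei$meta, "data/meta_meiocyte.tsv")
write_tsv(counts_mei$truth, "data/truth_de.tsv")
write_tsv(cbind(gene_id = rownames(counts_som$counts), counts_som$counts),
          "data/counts_somatic.tsv")
write_tsv(sr$reads, "data/srna_reads.tsv")
write_tsv(sr$truth, "data/srna_truth.tsv")

message(sprintf(
  "done: %d transcripts (%d coding / %d noncoding), %d scaffolds, %d sRNA reads",
  length(transcripts), sum(truth$true_class == "coding"),
  sum(truth$true_class == "noncoding"), length(gg$genome), nrow(sr$reads)))
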