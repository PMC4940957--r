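#!/usr/bin/env Rscript
# Step 2 — gene identification and lncRNA classification: the ordered
# translated-similarity cascade assigns protein-coding identities; the
# remaining (unidentified) transcripts go through the dual coding-potential
# consensus (CPAT-like p <= 0.3 AND CPC-like d <= -1) and the genome-hit
# flag.

source("analysis/00_config.R")

transcripts <- readDNAStringSet(file.path(DATA, "transcripts.fa"))
genome <- readDNAStringSet(file.path(DATA, "genome.fa"))
db_names <- c("tair10", "ha412", "haxrq", "refseq")
dbs <- lapply(db_names, function(nm) {
  readAAStringSet(file.path(DATA, paste0("peptides_", nm, ".fa")))
})
names(dbs) <- db_names
truth <- read_tsv("data/truth_transcripts.tsv")

message("identification cascade (bit >= 90, E <= 1e-6) ...")
asg <- identify_transcripts(transcripts, dbs)
write_tsv(asg, "identity_assignments.tsv")
message(sprintf("identified %d of %d transcripts (%s)",
                sum(asg$status == "identified"), nrow(asg),
                paste(names(table(asg$source_db)),
                      table(asg$source_db), collapse = ", ")))

message("training the coding-potential models on an independent labeled set ...")
tr <- gen_transcripts(cfg_train)
dbs_train <- gen_peptide_dbs(tr$transcripts, tr$truth, cfg_train)
model <- train_codepot(tr$transcripts, tr$truth$true_class == "coding",
                       dbs_train)

message("assessing unidentified transcripts ...")
unid <- transcripts[asg$transcript_id[asg$status == "unidentified"]]
ass <- assess_transcripts(unid, model, dbs)
write_tsv(ass, "coding_assessment.tsv")

message("genome-hit flags ...")
gh <- genome_hit(transcripts, genome)
classes <- data.frame(
  gene_id = names(transcripts),
  coding_class = "protein-coding",
  genome_hit = unname(gh),
  stringsAsFactors = FALSE)
classes$coding_class[match(ass$transcript_id, classes$gene_id)] <- ass$call
write_tsv(classes, "gene_classes.tsv")

recov <- mean((truth$true_class == "coding" &
                 classes$coding_class == "protein-coding") |
              (truth$true_class == "noncoding" &
                 classes$coding_class == "lncRNA"))
message(sprintf("class counts: %s | label recovery vs ground truth: %.1f %%",
                paste(names(table(classes$coding_class)),
                      table(classes$coding_class), collapse = ", "),
                100 * recov))
message(sprintf("lncRNAs with genome hit: %d / %d",
                sum(classes$genome_hit & classes$coding_class == "lncRNA"),
                sum(classes$coding_class == "lncRNA")))
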