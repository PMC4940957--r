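# Shared settings for the analysis workflow. Sourced by every numbered
# script; everything downstream is deterministic given this configuration.

library(meiolnc)
suppressPackageStartupMessages(library(Biostrings))

RESULTS <- "results"
DATA <- file.path(RESULTS, "data")
dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

# Study conditions: 400 assembled transcripts (half with planted coding
# structure), 3 genotypes x 2 replicates, 10 % planted DE at |log2FC| = 2,
# NB dispersion 0.1, a genome draft missing 5 % of transcripts, and an sRNA
# population with a 24-nt mode and a 0.6 5'-A bias.
STUDY_SEED <- 20160711 %% 100000L
cfg_study <- synth_config(seed = STUDY_SEED)

# Independent labeled set for training the coding-potential models.
cfg_train <- synth_config(n_coding = 100L, n_noncoding = 100L,
                          seed = STUDY_SEED + 1L)

write_tsv <- function(df, name) {
  utils::write.table(df, file.path(RESULTS, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
read_tsv <- function(name) {
  utils::read.delim(file.path(RESULTS, name), stringsAsFactors = FALSE)
}
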