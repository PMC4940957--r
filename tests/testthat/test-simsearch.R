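# Translated/nucleotide local similarity search, the identification cascade,
# and identifier collapsing.

test_that("six-frame translation follows the standard code", {
  expect_identical(unname(translate_six_frames("ATGAAATAA")["+1"]), "MK*")
  expect_true(all(translate_six_frames("") == ""))
  # codons containing N become X
  expect_identical(unname(translate_six_frames("ATGAANTAA")["+1"]), "MX*")
  expect_error(translate_six_frames("ATGQAA"), "position 4")
})

test_that("frame -1 equals frame +1 of the reverse complement", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_dna_chr(300)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_identical(translate_six_frames(s)[["-1"]],
                     translate_six_frames(rc)[["+1"]])
  }
})

test_that("self-alignment scores the diagonal; disjoint alphabets score 0", {
  sc <- scoring_peptide()
  pep <- "MKVLWAALLG"
  hit <- local_align(pep, pep, sc)
  diag_sum <- sum(diag(sc$matrix[strsplit(pep, "")[[1]], strsplit(pep, "")[[1]]]))
  expect_equal(hit$raw_score, diag_sum)
  scn <- scoring_nucleotide("+5/-4")
  expect_equal(local_align("AAAA", "CCCC", scn)$raw_score, 0)
})

test_that("local alignment equals the brute-force DP oracle", {
  sc <- scoring_peptide()
  aa <- rownames(sc$matrix)[1:20]  # standard residues
  set.seed(99)
  for (i in 1:60) {
    a <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    expect_equal(local_align(a, b, sc)$raw_score,
                 oracle_sw(a, b, sc$matrix, sc$gap_opening, sc$gap_extension),
                 info = paste(a, b))
  }
  scn <- scoring_nucleotide()
  for (i in 1:60) {
    a <- random_dna_chr(sample(5:30, 1))
    b <- random_dna_chr(sample(5:30, 1))
    expect_equal(local_align(a, b, scn)$raw_score,
                 oracle_sw(a, b, scn$matrix, scn$gap_opening,
                           scn$gap_extension),
                 info = paste(a, b))
  }
})

test_that("bit score and E-value follow the Karlin-Altschul form", {
  sc <- scoring_peptide()
  ka <- karlin_altschul(100, sc, 50, 200, 10)
  expect_equal(ka$bit_score, (0.267 * 100 - log(0.041)) / log(2))
  expect_equal(ka$e_value, 50 * 200 * 10 * 2^(-ka$bit_score))
})

test_that("the cascade assigns the first database that passes and stops", {
  ts <- tiny_set()
  # db1 and db2 both contain the peptide of the first coding transcript;
  # the cascade must credit db1 and never consult db2
  pep <- ts$dbs[[1]][1]
  dbs <- list(first = Biostrings::AAStringSet(setNames(as.character(pep), "p1")),
              second = Biostrings::AAStringSet(setNames(as.character(pep), "p2")))
  tx1 <- names(ts$dbs[[1]])[1]
  tx1 <- sub("^pep_", "", tx1)
  asg <- identify_transcripts(ts$transcripts[tx1], dbs)
  expect_identical(asg$status, "identified")
  expect_identical(asg$source_db, "first")
  expect_identical(asg$identifier, "p1")
  # a transcript whose peptide sits only in the last database still resolves
  dbs3 <- list(first = ts$dbs[[2]], second = ts$dbs[[3]], third = ts$dbs[[1]])
  asg3 <- identify_transcripts(ts$transcripts[tx1], dbs3)
  expect_identical(asg3$source_db, "third")
  expect_error(identify_transcripts(ts$transcripts[tx1], list()),
               "empty database")
})

test_that("raising the bit threshold never grows the identified set", {
  ts <- tiny_set()
  sub <- ts$transcripts[c(1:6, 17:22)]
  a90 <- identify_transcripts(sub, ts$dbs, bit_min = 90)
  a200 <- identify_transcripts(sub, ts$dbs, bit_min = 200)
  a999 <- identify_transcripts(sub, ts$dbs, bit_min = 1e6)
  id90 <- a90$transcript_id[a90$status == "identified"]
  id200 <- a200$transcript_id[a200$status == "identified"]
  expect_true(all(id200 %in% id90))
  expect_identical(a999$status, rep("unidentified", length(sub)))
})

test_that("identification separates planted coding from shuffled noncoding", {
  ts <- tiny_set()
  asg <- identify_transcripts(ts$transcripts, ts$dbs)
  expect_identical(asg$status == "identified",
                   ts$truth$true_class == "coding")
  # identified entries carry identifier + source, unidentified carry neither
  ided <- asg$status == "identified"
  expect_true(all(!is.na(asg$identifier[ided])))
  expect_true(all(!is.na(asg$source_db[ided])))
  expect_true(all(is.na(asg$identifier[!ided])))
})

test_that("collapsing sums counts within identifier groups and conserves reads", {
  asg <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    status = c("identified", "identified", "identified", "unidentified",
               "unidentified"),
    identifier = c("pA", "pA", "pB", NA, NA),
    source_db = c("db1", "db1", "db2", NA, NA),
    stringsAsFactors = FALSE)
  counts <- matrix(c(3, 4, 5, 1, 2,
                     10, 20, 30, 40, 50), ncol = 2,
                   dimnames = list(paste0("t", 1:5), c("s1", "s2")))
  col <- collapse_by_identifier(asg, counts)
  expect_equal(nrow(col$genes), 4)  # {t1,t2}, {t3}, {t4}, {t5}
  expect_equal(unname(col$counts["db1:pA", ]), c(7, 30))
  expect_equal(colSums(col$counts), colSums(counts))
  # all-distinct identifiers: row count preserved
  asg2 <- asg
  asg2$identifier <- c("pA", "pC", "pB", NA, NA)
  col2 <- collapse_by_identifier(asg2, counts)
  expect_equal(nrow(col2$genes), 5)
  expect_error(collapse_by_identifier(rbind(asg, asg[1, ]), counts),
               "duplicate")
})

test_that("a planted sharing partition collapses to its block count", {
  set.seed(31)
  n <- 60
  blocks <- sample(1:22, n, replace = TRUE)  # partition with <= 22 blocks
  asg <- data.frame(transcript_id = sprintf("t%02d", 1:n),
                    status = "identified",
                    identifier = sprintf("pep%02d", blocks),
                    source_db = "db1", stringsAsFactors = FALSE)
  counts <- matrix(rpois(n * 2, 10), ncol = 2,
                   dimnames = list(asg$transcript_id, c("s1", "s2")))
  col <- collapse_by_identifier(asg, counts)
  expect_equal(nrow(col$genes), length(unique(blocks)))
  expect_equal(colSums(col$counts), colSums(counts))
})
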