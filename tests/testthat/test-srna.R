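# Small-RNA population processing: filtering, redundancy, 5' bias,
# best-stratum mapping, class association and family assignment.

test_that("length filtering collapses duplicates and conserves reads", {
  raw <- c(rep("ACGTACGTACGTACGTACGTACGT", 3),  # 24 nt, x3
           "ACGTACGTACGTACGTACG",               # 19 nt -> dropped
           "TTTTTTTTTTTTTTTTTTTTT")             # 21 nt
  fr <- filter_reads(raw)
  expect_equal(nrow(fr$reads), 2)
  expect_equal(fr$reads$mult[fr$reads$length == 24], 3)
  expect_equal(nrow(fr$dropped), 1)
  expect_equal(sum(fr$reads$mult) + sum(fr$dropped$mult), length(raw))
})

test_that("redundancy profile distinguishes unique from repeated sequences", {
  reads <- data.frame(seq = c("A", "B", "C", "D"),
                      length = c(21L, 21L, 24L, 24L),
                      mult = c(5L, 1L, 1L, 1L))
  rp <- redundancy_profile(reads)
  expect_equal(rp$unique[rp$length == 21], 1)
  expect_equal(rp$redundant[rp$length == 21], 5)
  expect_equal(rp$unique[rp$length == 24], 2)
  expect_equal(rp$redundant[rp$length == 24], 0)
})

test_that("5' bias handles degenerate and trivial cases", {
  reads <- data.frame(seq = c("AAAA", "ACGT"), length = c(24L, 24L),
                      mult = c(3L, 1L))
  b <- five_prime_bias(reads, 24)
  expect_equal(unname(b["A"]), 1)
  expect_error(five_prime_bias(reads, 21), "no reads")
})

test_that("best-stratum mapping obeys the --best --strata contract", {
  ref <- Biostrings::DNAStringSet(c(
    genome1 = "TTTTTTACGTACGTACGTACGTACGTACGTTTTTTT",
    tx1 = "CCCCCCACGTACGTACGTACTTACGTACGCCCCCC"))
  kind <- c("genome", "transcript")
  # exact in genome, 1 mismatch in transcript: only the genome hit survives
  rd <- data.frame(seq = "ACGTACGTACGTACGTACGTACG", length = 23L, mult = 1L)
  mp <- map_srna(rd, ref, kind)
  expect_true(all(mp$mismatch == 0))
  expect_true(all(mp$target_id == "genome1"))
  # a read exact in one transcript only: single 0-mismatch hit
  rd2 <- data.frame(seq = "CCCCCCACGTACGTACGTAC", length = 20L, mult = 1L)
  mp2 <- map_srna(rd2, ref, kind)
  expect_equal(nrow(mp2), 1)
  expect_equal(mp2$mismatch, 0)
  expect_equal(mp2$target_kind, "transcript")
  expect_error(map_srna(rd, Biostrings::DNAStringSet(), character(0)),
               "empty reference")
})

test_that("mapping equals an exhaustive scan oracle", {
  ts <- tiny_set()
  refs <- c(ts$genome$genome[1:2], ts$transcripts[c(1, 17)])
  kinds <- c("genome", "genome", "transcript", "transcript")
  cfg <- synth_config(seed = 23L)
  r <- gen_srna_reads(ts$transcripts[c(1, 17)], cfg, n_reads = 40L)
  mp <- map_srna(r$reads, refs, kinds)
  ref_chr <- as.character(refs)
  for (sq in unique(r$reads$seq)) {
    got <- mp[mp$seq == sq, c("target_id", "position", "strand", "mismatch")]
    want <- oracle_srna_scan(sq, ref_chr)
    got <- got[order(got$target_id, got$position, got$strand), ]
    want <- want[order(want$target_id, want$position, want$strand), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = sq)
  }
})

test_that("class association applies the mixed-reference rule", {
  classes <- data.frame(gene_id = c("tx1", "tx2"),
                        coding_class = c("lncRNA", "protein-coding"),
                        stringsAsFactors = FALSE)
  mapping <- data.frame(
    seq = c("r1", "r2", "r3"), mult = c(2L, 1L, 4L),
    target_id = c("tx1", "scaff1", "tx1"),
    target_kind = c("transcript", "genome", "transcript"),
    position = c(0L, 5L, 10L), strand = c("+", "+", "-"),
    mismatch = c(0L, 0L, 0L), stringsAsFactors = FALSE)
  mapping$seq <- c(strrep("A", 21), strrep("C", 24), strrep("G", 24))
  a <- associate_srna(mapping, classes)
  expect_true(a$srna_flag[["tx1"]])
  expect_false(a$srna_flag[["tx2"]])  # no transcript-level best hit
  sbc <- a$strand_by_class
  expect_equal(sbc$plus_fraction[sbc$length == 21], 1)
  expect_equal(sbc$plus_fraction[sbc$length == 24], 0)
})

test_that("planted strand structure shows up in the class proportions", {
  ts <- tiny_set()
  pre <- ts$transcripts[c(1:4, 17:20)]
  cfg <- synth_config(srna_length_weights = c("21" = 0.4, "24" = 0.6),
                      seed = 29L)
  r <- gen_srna_reads(pre, cfg, n_reads = 600L)
  refs <- pre
  kinds <- rep("transcript", length(pre))
  mp <- map_srna(r$reads, refs, kinds)
  classes <- data.frame(gene_id = names(pre),
                        coding_class = rep(c("protein-coding", "lncRNA"),
                                           each = 4),
                        stringsAsFactors = FALSE)
  a <- associate_srna(mp, classes)
  sbc <- a$strand_by_class
  p21 <- sum(sbc$plus_fraction[sbc$length == 21] *
               sbc$reads[sbc$length == 21]) / sum(sbc$reads[sbc$length == 21])
  p24 <- sum(sbc$plus_fraction[sbc$length == 24] *
               sbc$reads[sbc$length == 24]) / sum(sbc$reads[sbc$length == 24])
  n24 <- sum(sbc$reads[sbc$length == 24])
  expect_equal(p21, 1)  # miRNA-like reads are single-strand by construction
  expect_lt(abs(p24 - 0.5), 3 * sqrt(0.25 / n24) + 0.05)
})

test_that("miRNA family assignment is exact with ambiguous ties unassigned", {
  fams <- Biostrings::DNAStringSet(c(
    "miR166_1" = "TCGGACCAGGCTTCATTCCCC",
    "miR396_1" = "TTCCACAGCTTTCTTGAACTG",
    "miR319_1" = "TTGGACTGAAGGGAGCTCCCT"))
  reads <- data.frame(
    seq = c("TCGGACCAGGCTTCATTCCCC",   # exact miR166
            "TTCCACAGCTTTCTTGAACTT",   # 1 mm to miR396
            "AAAAAAAAAAAAAAAAAAAAA"),  # nothing
    mult = c(10L, 5L, 2L), stringsAsFactors = FALSE)
  fa <- mirna_family_assign(reads, fams)
  expect_identical(fa$assigned, c("miR166", "miR396", NA))
  expect_equal(fa$counts$reads[fa$counts$family == "miR166"], 10)
  # equal-distance tie between two families stays unassigned
  fams2 <- Biostrings::DNAStringSet(c(
    famA_1 = "AAAAAAAAAAAAAAAAAAAAC", famB_1 = "AAAAAAAAAAAAAAAAAAAAG"))
  rd <- data.frame(seq = "AAAAAAAAAAAAAAAAAAAAT", mult = 1L)
  expect_true(is.na(mirna_family_assign(rd, fams2)$assigned))
  # planted mixture recovered exactly
  reads3 <- data.frame(seq = rep(as.character(fams), c(7, 3, 2)),
                       mult = rep(1L, 12))
  fa3 <- mirna_family_assign(reads3, fams)
  expect_equal(sort(fa3$counts$reads), c(2, 3, 7))
})
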