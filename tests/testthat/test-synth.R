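# Synthetic-data generator: determinism, planted structure, and the
# statistical properties the downstream analysis assumes.

test_that("configuration is validated field by field", {
  expect_error(synth_config(length_range = c(150L, 900L)), "length_range")
  expect_error(synth_config(genome_dropout = 1.2), "genome_dropout")
  expect_error(synth_config(de_fraction = -0.1), "de_fraction")
  expect_error(synth_config(srna_length_weights = c("20" = 0.6, "24" = 0.4)),
               "srna_length_weights")
  expect_error(synth_config(nb_dispersion = -1), "nb_dispersion")
})

test_that("empty configuration yields an empty transcript set", {
  g <- gen_transcripts(synth_config(n_coding = 0L, n_noncoding = 0L))
  expect_length(g$transcripts, 0)
  expect_equal(nrow(g$truth), 0)
})

test_that("generation is byte-identical under the same seed", {
  cfg <- tiny_cfg()
  g1 <- gen_transcripts(cfg)
  g2 <- gen_transcripts(cfg)
  expect_identical(as.character(g1$transcripts), as.character(g2$transcripts))
  c1 <- gen_counts(g1$truth$id, cfg)
  c2 <- gen_counts(g1$truth$id, cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$truth$true_de, c2$truth$true_de)
})

test_that("planted ORF structure is recovered by an independent frame scan", {
  ts <- tiny_set()
  seqs <- as.character(ts$transcripts)
  lens <- vapply(seqs, oracle_longest_orf_len, integer(1))
  coding <- ts$truth$true_class == "coding"
  # every coding transcript carries an ORF >= 300 nt (the planted floor)
  expect_true(all(lens[coding] >= 300))
  # scan agrees with the recorded planted length (the planted ORF is maximal)
  expect_true(all(lens[coding] >= ts$truth$planted_orf_length[coding]))
  # noncoding transcripts respect the ORF cap on both strands
  expect_true(all(lens[!coding] <= ts$cfg$noncoding_orf_cap))
})

test_that("noncoding transcripts preserve composition up to stop injection", {
  # the dinucleotide shuffle itself is exactly dinucleotide-preserving
  set.seed(42)
  for (i in 1:5) {
    s <- random_dna_chr(600)
    sh <- meiolnc:::dinucleotide_shuffle(s)
    expect_identical(sort(names(count_dinucleotides(s))),
                     sort(names(count_dinucleotides(sh))))
    expect_equal(as.integer(count_dinucleotides(sh)[names(count_dinucleotides(s))]),
                 as.integer(count_dinucleotides(s)))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("genome dropout is exact and verified by substring search", {
  ts <- tiny_set()
  cfg0 <- synth_config(n_coding = 8L, n_noncoding = 8L, genome_dropout = 0,
                       seed = 5L)
  g0 <- gen_genome(ts$transcripts[1:16], cfg0)
  joined <- paste(as.character(g0$genome), collapse = "NN")
  for (id in names(ts$transcripts)[1:16]) {
    s <- as.character(ts$transcripts[[id]])
    found <- grepl(s, joined, fixed = TRUE) ||
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))), joined, fixed = TRUE)
    expect_true(found, info = id)
  }
  cfg1 <- synth_config(n_coding = 8L, n_noncoding = 8L, genome_dropout = 1,
                       seed = 5L)
  g1 <- gen_genome(ts$transcripts[1:16], cfg1)
  joined1 <- paste(as.character(g1$genome), collapse = "NN")
  expect_false(any(vapply(names(ts$transcripts)[1:16], function(id) {
    grepl(as.character(ts$transcripts[[id]]), joined1, fixed = TRUE)
  }, logical(1))))
  # fractional dropout: exactly round(dropout * n) absent
  cfgd <- synth_config(n_coding = 10L, n_noncoding = 10L,
                       genome_dropout = 0.1, seed = 9L)
  gd <- gen_transcripts(cfgd)
  gg <- gen_genome(gd$transcripts, cfgd)
  expect_equal(sum(!gg$placement$in_genome), 2)
  joined_d <- paste(as.character(gg$genome), collapse = "NN")
  absent <- vapply(names(gd$transcripts), function(id) {
    s <- as.character(gd$transcripts[[id]])
    !(grepl(s, joined_d, fixed = TRUE) ||
        grepl(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s))), joined_d, fixed = TRUE))
  }, logical(1))
  expect_equal(sum(absent), 2)
  expect_identical(sort(names(absent)[absent]),
                   sort(gg$placement$id[!gg$placement$in_genome]))
})

test_that("placement map coordinates are exact", {
  ts <- tiny_set()
  pl <- ts$genome$placement
  sc <- as.character(ts$genome$genome)
  for (i in which(pl$in_genome)) {
    emb <- substr(sc[[pl$scaffold[i]]], pl$start[i] + 1L, pl$end[i])
    orig <- as.character(ts$transcripts[[pl$id[i]]])
    if (pl$strand[i] == "-") {
      orig <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(orig)))
    }
    expect_identical(emb, orig)
  }
})

test_that("count simulation plants the requested DE structure", {
  cfg <- synth_config(de_fraction = 0, seed = 3L)
  gc0 <- gen_counts(sprintf("g%03d", 1:50), cfg)
  expect_false(any(gc0$truth$true_de))
  cfg2 <- synth_config(de_fraction = 0.2, seed = 3L)
  gc2 <- gen_counts(sprintf("g%04d", 1:1000), cfg2)
  expect_equal(sum(gc2$truth$true_de), 200)
  expect_true(all(gc2$counts >= 0))
  expect_true(all(gc2$counts == round(gc2$counts)))
})

test_that("zero dispersion gives the Poisson mean-variance limit", {
  cfg <- synth_config(nb_dispersion = 0, de_fraction = 0, seed = 21L,
                      n_genotypes = 1L, n_replicates = 6L)
  gc <- gen_counts(sprintf("g%05d", 1:10000), cfg)
  # remove the library-size factor spread: compare within-gene variance of
  # scaled counts to the scaled mean
  sf <- colSums(gc$counts) / mean(colSums(gc$counts))
  sc <- sweep(gc$counts, 2, sf, "/")
  m <- rowMeans(sc)
  v <- apply(sc, 1, var)
  # regression of variance on mean should have slope ~1 (Poisson)
  slope <- coef(lm(v ~ m))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.15)
})

test_that("small-RNA reads follow the configured length and strand rules", {
  ts <- tiny_set()
  cfg24 <- synth_config(srna_length_weights = c("24" = 1), seed = 5L)
  r24 <- gen_srna_reads(ts$transcripts, cfg24, n_reads = 200L)
  expect_true(all(r24$reads$length == 24))
  cfgA <- synth_config(srna_length_weights = c("24" = 1),
                       fiveprime_A_bias = 1, seed = 5L)
  rA <- gen_srna_reads(ts$transcripts, cfgA, n_reads = 200L)
  expect_true(all(substr(rA$reads$seq, 1, 1) == "A"))
  # reads are exact substrings of their precursor on the recorded strand
  r <- gen_srna_reads(ts$transcripts, ts$cfg, n_reads = 300L)
  for (i in seq_len(nrow(r$reads))) {
    src <- as.character(ts$transcripts[[r$truth$source[i]]])
    if (r$truth$strand[i] == "-") {
      src <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(src)))
    }
    expect_true(grepl(r$reads$seq[i], src, fixed = TRUE))
  }
  # single-strand rule for the miRNA-like lengths
  expect_true(all(r$truth$strand[r$reads$length <= 22] == "+"))
})

test_that("5'-adenosine bias of 24-nt reads matches the configured rate", {
  ts <- tiny_set()
  cfg <- synth_config(fiveprime_A_bias = 0.6, seed = 17L)
  r <- gen_srna_reads(ts$transcripts, cfg, n_reads = 10000L)
  sel <- r$reads$length == 24
  frac <- sum(r$reads$mult[sel & substr(r$reads$seq, 1, 1) == "A"]) /
    sum(r$reads$mult[sel])
  se <- sqrt(0.6 * 0.4 / sum(sel))
  expect_lt(abs(frac - 0.6), 3 * se)
})

test_that("TE/NAT generation honours zero-insertion requests", {
  ts <- tiny_set()
  nc <- ts$truth$id[ts$truth$true_class == "noncoding"]
  tn <- gen_te_nat(ts$transcripts, ts$cfg, noncoding_ids = nc,
                   n_te = 0L, n_nat = 0L)
  expect_equal(nrow(tn$truth_te), 0)
  expect_equal(nrow(tn$truth_nat), 0)
  expect_identical(as.character(tn$transcripts),
                   as.character(ts$transcripts))
  ann <- annotate_te(tn$transcripts[nc[1:4]], tn$te_library)
  expect_true(all(is.na(ann$annotation$te_family)))
})
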