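# Synthetic-data generator: produces every input the pipeline consumes
# (transcripts, genome draft, count matrices, small-RNA reads, TE library and
# NAT database) with the statistical structure the analysis assumes, plus a
# ground-truth table per generated record.

TE_FAMILY_CODES <- c("DH", "DT", "DTA", "DTC", "DTH", "DTM", "DXX",
                     "RI", "RIL", "RLC", "RLG", "RLR", "RLX", "RX")

#' Configuration for the synthetic-data generator
#'
#' Collects and validates the generative knobs: numbers of coding and
#' noncoding transcripts, transcript length range (> 200 nt, the lncRNA
#' length precondition), mean planted ORF length, the fraction of transcripts
#' omitted from the synthetic genome draft, the genotype design (3 genotypes
#' x 2 replicates by default, mirroring the study design), the planted
#' differential-expression fraction and effect size, the negative-binomial
#' dispersion, the small-RNA read-length weights (mode at 24 nt) and the
#' 5'-terminal adenosine bias of 24-nt reads.
#'
#' @param n_coding,n_noncoding numbers of coding / noncoding transcripts.
#' @param length_range integer vector of length 2, transcript length bounds in
#'   nt; the minimum must exceed 200.
#' @param orf_length_mean mean planted ORF length (nt) for coding transcripts.
#' @param noncoding_orf_cap maximum ORF length (nt) tolerated in noncoding
#'   transcripts; longer chance ORFs are disrupted by stop-codon injection.
#' @param genome_dropout fraction of transcripts omitted from the genome.
#' @param n_genotypes,n_replicates count-matrix design (defaults 3 and 2).
#' @param de_fraction fraction of genes with a planted expression difference
#'   between the domesticated and wild genotypes.
#' @param log2_effect planted log2 fold change for differential genes.
#' @param nb_dispersion negative-binomial dispersion phi (>= 0; 0 = Poisson).
#' @param mean_count baseline mean unique-read count per gene and sample.
#' @param srna_length_weights named numeric vector over lengths 20..25 summing
#'   to 1 with its mode at 24 nt.
#' @param fiveprime_A_bias fraction of 24-nt reads starting with adenosine.
#' @param seed single integer; every generator stage derives an independent
#'   stream from (seed, stage name).
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_coding = 200L,
                         n_noncoding = 200L,
                         length_range = c(300L, 1200L),
                         orf_length_mean = 600L,
                         noncoding_orf_cap = 150L,
                         genome_dropout = 0.05,
                         n_genotypes = 3L,
                         n_replicates = 2L,
                         de_fraction = 0.1,
                         log2_effect = 2,
                         nb_dispersion = 0.1,
                         mean_count = 100,
                         srna_length_weights = c("20" = 0.08, "21" = 0.18,
                                                 "22" = 0.06, "23" = 0.08,
                                                 "24" = 0.50, "25" = 0.10),
                         fiveprime_A_bias = 0.6,
                         seed = 1L) {
  check_count(n_coding, "n_coding")
  check_count(n_noncoding, "n_noncoding")
  if (length(length_range) != 2L || any(length_range != round(length_range)) ||
      length_range[1] > length_range[2]) {
    stop_config("length_range", "must be two integers min <= max")
  }
  if (length_range[1] <= 200) {
    stop_config("length_range", "minimum must exceed 200 nt")
  }
  check_count(orf_length_mean, "orf_length_mean", min = 60L)
  check_count(noncoding_orf_cap, "noncoding_orf_cap", min = 30L)
  check_fraction(genome_dropout, "genome_dropout")
  check_count(n_genotypes, "n_genotypes", min = 1L)
  check_count(n_replicates, "n_replicates", min = 1L)
  check_fraction(de_fraction, "de_fraction")
  if (!is.numeric(log2_effect) || length(log2_effect) != 1L) {
    stop_config("log2_effect", "must be a single number")
  }
  if (!is.numeric(nb_dispersion) || length(nb_dispersion) != 1L ||
      nb_dispersion < 0) {
    stop_config("nb_dispersion", "must be a single number >= 0")
  }
  if (!is.numeric(mean_count) || length(mean_count) != 1L || mean_count <= 0) {
    stop_config("mean_count", "must be a single positive number")
  }
  w <- srna_length_weights
  if (is.null(names(w)) || !all(names(w) %in% as.character(20:25)) ||
      any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop_config("srna_length_weights",
                "must be named over lengths 20..25 and sum to 1")
  }
  if (names(w)[which.max(w)] != "24") {
    stop_config("srna_length_weights", "must have its mode at 24 nt")
  }
  check_fraction(fiveprime_A_bias, "fiveprime_A_bias")
  check_count(seed, "seed")
  structure(list(n_coding = as.integer(n_coding),
                 n_noncoding = as.integer(n_noncoding),
                 length_range = as.integer(length_range),
                 orf_length_mean = as.integer(orf_length_mean),
                 noncoding_orf_cap = as.integer(noncoding_orf_cap),
                 genome_dropout = genome_dropout,
                 n_genotypes = as.integer(n_genotypes),
                 n_replicates = as.integer(n_replicates),
                 de_fraction = de_fraction,
                 log2_effect = log2_effect,
                 nb_dispersion = nb_dispersion,
                 mean_count = mean_count,
                 srna_length_weights = w,
                 fiveprime_A_bias = fiveprime_A_bias,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Built-in plant-like codon usage table
#'
#' A fixed, biased codon frequency table over the 61 sense codons, shipped as
#' a plain-text data file so coding-sequence generation is reproducible
#' without external downloads. The bias is strong enough that in-frame
#' hexamer usage separates planted coding sequence from shuffled background.
#'
#' @return named numeric vector of relative frequencies summing to 1.
#' @export
codon_usage_table <- function() {
  path <- system.file("extdata", "codon_usage_plant.tsv", package = "meiolnc")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  w <- setNames(tab$weight, tab$codon)
  w / sum(w)
}

random_dna <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Altschul-Erickson dinucleotide-preserving shuffle. Keeps the exact multiset
# of dinucleotides (hence mono- and dinucleotide composition) while
# randomizing higher-order structure.
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 3L) return(seq)
  edges <- split(s[-1], s[-n])      # outgoing edge targets per vertex
  verts <- names(edges)
  last <- s[n]
  repeat {
    # pick one candidate "last edge" per non-terminal vertex, then check the
    # chosen edges form paths that all reach the terminal vertex
    pick <- vapply(verts, function(v) {
      if (v == last) NA_character_ else sample(edges[[v]], 1L)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      cur <- v
      steps <- 0L
      while (cur != last && steps < 8L) {
        cur <- pick[[cur]]
        if (is.na(cur) || !cur %in% verts) break
        steps <- steps + 1L
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  ordered <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last) return(sample(e))
    li <- match(pick[[v]], e)
    rest <- e[-li]
    c(if (length(rest)) sample(rest), pick[[v]])
  })
  names(ordered) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# Disrupt any ORF longer than `cap` (both strands) by replacing an internal
# codon with TAA in the ORF's own frame. Changes at most a handful of codons.
enforce_orf_cap <- function(seq, cap) {
  for (iter in 1:200) {
    o <- longest_orf(seq)
    if (is.null(o) || o$length <= cap) return(seq)
    work <- if (o$strand == "+") seq else revcomp_chr(seq)
    ncod <- o$length / 3L
    codon_i <- max(2L, min(ncod - 1L, sample(2:(ncod - 1L), 1L)))
    pos <- o$start + (codon_i - 1L) * 3L + 1L  # 1-based on `work`
    substr(work, pos, pos + 2L) <- "TAA"
    seq <- if (o$strand == "+") work else revcomp_chr(work)
  }
  seq
}

sample_coding_seq <- function(len, orf_len, codon_w) {
  orf_len <- max(9L, (orf_len %/% 3L) * 3L)
  orf_len <- min(orf_len, (len %/% 3L) * 3L)
  n_inner <- orf_len / 3L - 2L
  inner <- if (n_inner > 0) {
    paste(sample(names(codon_w), n_inner, replace = TRUE, prob = codon_w),
          collapse = "")
  } else ""
  orf <- paste0("ATG", inner, sample(c("TAA", "TGA", "TAG"), 1L))
  flank_total <- len - nchar(orf)
  f5 <- if (flank_total > 0) sample(0:flank_total, 1L) else 0L
  paste0(if (f5 > 0) random_dna(f5) else "",
         orf,
         if (flank_total - f5 > 0) random_dna(flank_total - f5) else "")
}

#' Generate synthetic transcripts with ground truth
#'
#' Coding transcripts carry a planted ATG..stop ORF whose codons are drawn
#' from a biased plant-like codon table; noncoding transcripts are
#' dinucleotide-preserving shuffles of coding ones (so base composition alone
#' cannot separate the classes) with chance ORFs above the configured cap
#' disrupted by stop-codon injection. Deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `transcripts` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame: id, true_class, length, planted_orf_length).
#' @export
gen_transcripts <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_stage_seed(cfg$seed, "transcripts", {
    codon_w <- codon_usage_table()
    n <- cfg$n_coding + cfg$n_noncoding
    if (n == 0L) {
      return(list(transcripts = Biostrings::DNAStringSet(),
                  truth = data.frame(id = character(0),
                                     true_class = character(0),
                                     length = integer(0),
                                     planted_orf_length = integer(0))))
    }
    ids <- sprintf("TX%05d", seq_len(n))
    classes <- c(rep("coding", cfg$n_coding), rep("noncoding", cfg$n_noncoding))
    seqs <- character(n)
    orf_lens <- rep(NA_integer_, n)
    if (cfg$n_coding > 0) {
      for (i in seq_len(cfg$n_coding)) {
        len <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
        ol <- round(stats::rnorm(1, cfg$orf_length_mean, cfg$orf_length_mean / 6))
        ol <- max(300L, (as.integer(ol) %/% 3L) * 3L)
        ol <- min(ol, (len %/% 3L) * 3L)
        seqs[i] <- sample_coding_seq(len, ol, codon_w)
        orf_lens[i] <- ol
      }
    }
    if (cfg$n_noncoding > 0) {
      for (j in seq_len(cfg$n_noncoding)) {
        i <- cfg$n_coding + j
        src <- if (cfg$n_coding > 0) {
          seqs[sample.int(cfg$n_coding, 1L)]
        } else {
          random_dna(sample(cfg$length_range[1]:cfg$length_range[2], 1L))
        }
        seqs[i] <- enforce_orf_cap(dinucleotide_shuffle(src),
                                   cfg$noncoding_orf_cap)
      }
    }
    tx <- Biostrings::DNAStringSet(setNames(seqs, ids))
    list(transcripts = tx,
         truth = data.frame(id = ids, true_class = classes,
                            length = nchar(seqs),
                            planted_orf_length = orf_lens,
                            stringsAsFactors = FALSE))
  })
}

#' Embed transcripts in a synthetic genome draft
#'
#' Each non-dropped transcript is embedded verbatim (possibly
#' reverse-complemented) in a scaffold between random flanks; exactly
#' `round(genome_dropout * n)` transcripts are absent from the draft,
#' emulating an incomplete genome assembly.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param cfg a [synth_config()].
#' @param per_scaffold approximate number of transcripts per scaffold.
#' @return list with `genome` (DNAStringSet of scaffolds) and `placement`
#'   (data.frame: id, in_genome, scaffold, start, end (0-based half-open on
#'   the scaffold), strand).
#' @export
gen_genome <- function(transcripts, cfg, per_scaffold = 10L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(transcripts) == 0L) stop("transcripts must be non-empty", call. = FALSE)
  with_stage_seed(cfg$seed, "genome", {
    n <- length(transcripts)
    ids <- names(transcripts)
    n_drop <- round(cfg$genome_dropout * n)
    dropped <- if (n_drop > 0) sample(ids, n_drop) else character(0)
    keep <- setdiff(ids, dropped)
    placement <- data.frame(id = ids, in_genome = !(ids %in% dropped),
                            scaffold = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            strand = NA_character_, stringsAsFactors = FALSE)
    scaff_seqs <- character(0)
    if (length(keep) > 0) {
      order_keep <- sample(keep)
      groups <- split(order_keep,
                      ceiling(seq_along(order_keep) / per_scaffold))
      for (g in seq_along(groups)) {
        sc_name <- sprintf("scaffold%03d", g)
        parts <- character(0)
        pos <- 0L
        for (id in groups[[g]]) {
          flank <- random_dna(sample(100:300, 1L))
          parts <- c(parts, flank)
          pos <- pos + nchar(flank)
          strand <- sample(c("+", "-"), 1L)
          ins <- as.character(transcripts[[id]])
          if (strand == "-") ins <- revcomp_chr(ins)
          parts <- c(parts, ins)
          i <- match(id, placement$id)
          placement$scaffold[i] <- sc_name
          placement$start[i] <- pos
          placement$end[i] <- pos + nchar(ins)
          placement$strand[i] <- strand
          pos <- pos + nchar(ins)
        }
        parts <- c(parts, random_dna(sample(100:300, 1L)))
        scaff_seqs[sc_name] <- paste(parts, collapse = "")
      }
    } else {
      scaff_seqs <- setNames(vapply(1:3, function(i) random_dna(2000L),
                                    character(1)),
                             sprintf("scaffold%03d", 1:3))
    }
    list(genome = Biostrings::DNAStringSet(scaff_seqs), placement = placement)
  })
}

#' Simulate a unique-read count matrix with planted differential expression
#'
#' Counts are negative-binomial with gene-specific lognormal means, sample
#' library-size factors, and common dispersion `nb_dispersion` (Poisson when
#' 0). For planted differential genes the domesticated-genotype mean is
#' scaled by `2^log2_effect`.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param cfg a [synth_config()].
#' @param tissue tissue label recorded in the sample metadata.
#' @param stage RNG stage label; change it to draw an independent matrix
#'   (e.g. a somatic tissue) from the same seed.
#' @return list with `counts` (genes x samples integer matrix), `meta`
#'   (sample metadata data.frame) and `truth` (data.frame: id, true_de, mu).
#' @export
gen_counts <- function(gene_ids, cfg, tissue = "meiocyte", stage = "counts") {
  stopifnot(inherits(cfg, "synth_config"))
  with_stage_seed(cfg$seed, stage, {
    genotypes <- c("domesticated", "wild", "F1")[seq_len(cfg$n_genotypes)]
    meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        genotype = genotypes, stringsAsFactors = FALSE)
    meta <- meta[, c("genotype", "replicate")]
    meta$tissue <- tissue
    meta$sample <- sprintf("%s_%s_r%d", tissue, meta$genotype, meta$replicate)
    n <- length(gene_ids)
    n_de <- round(cfg$de_fraction * n)
    de <- rep(FALSE, n)
    if (n_de > 0) de[sample.int(n, n_de)] <- TRUE
    mu <- rlnorm(n, meanlog = log(cfg$mean_count), sdlog = 1)
    sf <- runif(nrow(meta), 0.7, 1.3)
    counts <- matrix(0L, nrow = n, ncol = nrow(meta),
                     dimnames = list(gene_ids, meta$sample))
    for (j in seq_len(nrow(meta))) {
      m <- mu * sf[j]
      if (meta$genotype[j] == "domesticated") {
        m[de] <- m[de] * 2^cfg$log2_effect
      }
      counts[, j] <- if (cfg$nb_dispersion == 0) {
        rpois(n, m)
      } else {
        rnbinom(n, mu = m, size = 1 / cfg$nb_dispersion)
      }
    }
    list(counts = counts, meta = meta,
         truth = data.frame(id = gene_ids, true_de = de, mu = mu,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate small-RNA reads from precursor transcripts
#'
#' Read lengths follow `srna_length_weights`; every read is an exact
#' substring of its precursor (on the sampled strand). Lengths 20-22 nt are
#' drawn single-strand (miRNA-like, from the '+' strand of the precursor)
#' while 23-25 nt reads come from both strands (siRNA-like). 24-nt reads
#' start with adenosine at exactly rate `fiveprime_A_bias` in expectation
#' (start positions are stratified by first base). Shorter miRNA-like reads
#' receive higher multiplicities, reproducing the redundancy contrast between
#' the 21-nt and 24-nt populations.
#'
#' @param transcripts named [Biostrings::DNAStringSet] of precursors.
#' @param cfg a [synth_config()].
#' @param n_reads number of read draws before collapsing to unique sequences.
#' @param precursor_ids optional subset of transcript names to draw from.
#' @return list with `reads` (data.frame: seq, length, mult) and `truth`
#'   (per unique read: source transcript and strand).
#' @export
gen_srna_reads <- function(transcripts, cfg, n_reads = 3000L,
                           precursor_ids = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_stage_seed(cfg$seed, "srna", {
    if (is.null(precursor_ids)) precursor_ids <- names(transcripts)
    pre <- as.character(transcripts[precursor_ids])
    lens <- as.integer(names(cfg$srna_length_weights))
    recs <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      L <- lens[sample.int(length(lens), 1L, prob = cfg$srna_length_weights)]
      src <- precursor_ids[sample.int(length(precursor_ids), 1L)]
      strand <- if (L <= 22L) "+" else sample(c("+", "-"), 1L)
      sseq <- if (strand == "+") pre[[src]] else revcomp_chr(pre[[src]])
      npos <- nchar(sseq) - L + 1L
      starts <- 1:npos
      first <- substring(sseq, starts, starts)
      if (L == 24L) {
        a_pos <- starts[first == "A"]
        o_pos <- starts[first != "A"]
        want_a <- runif(1) < cfg$fiveprime_A_bias
        pool <- if (want_a) a_pos else o_pos
        if (length(pool) == 0L) pool <- starts
        p <- pool[sample.int(length(pool), 1L)]
      } else {
        p <- starts[sample.int(npos, 1L)]
      }
      mult <- 1L + rpois(1, if (L <= 22L) 3 else 0.3)
      recs[[i]] <- data.frame(seq = substr(sseq, p, p + L - 1L),
                              length = L, mult = mult, source = src,
                              strand = strand, stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, recs)
    # collapse identical sequences; keep the first source/strand seen
    agg <- stats::aggregate(mult ~ seq, data = all, FUN = sum)
    firsts <- all[!duplicated(all$seq), c("seq", "length", "source", "strand")]
    reads <- merge(firsts, agg, by = "seq", sort = FALSE)
    list(reads = reads[, c("seq", "length", "mult")],
         truth = reads[, c("seq", "source", "strand")])
  })
}

#' Build ordered synthetic peptide databases from planted ORFs
#'
#' Translates the planted ORF of each coding transcript and distributes the
#' peptides across `db_names` (round-robin), emulating the ordered reference
#' peptide databases the identification cascade queries. Optionally plants a
#' sharing structure: transcripts listed together in `share_groups` point to
#' the same peptide identifier, so they collapse to one gene downstream.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param truth ground-truth data.frame from [gen_transcripts()].
#' @param cfg a [synth_config()].
#' @param db_names ordered database names (highest precedence first).
#' @return named list of [Biostrings::AAStringSet] in precedence order; the
#'   peptide of coding transcript `id` is named `pep_<id>`.
#' @export
gen_peptide_dbs <- function(transcripts, truth, cfg,
                            db_names = c("tair10", "ha412", "haxrq", "refseq")) {
  with_stage_seed(cfg$seed, "peptide_dbs", {
    coding <- truth$id[truth$true_class == "coding"]
    peps <- character(0)
    for (id in coding) {
      s <- as.character(transcripts[[id]])
      o <- longest_orf(s)
      if (is.null(o)) next
      w <- if (o$strand == "+") s else revcomp_chr(s)
      orf <- substr(w, o$start + 1L, o$end)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                               if.fuzzy.codon = "X"))
      peps[paste0("pep_", id)] <- sub("\\*$", "", aa)
    }
    dbs <- setNames(vector("list", length(db_names)), db_names)
    slot <- rep_len(seq_along(db_names), length(peps))
    for (k in seq_along(db_names)) {
      dbs[[k]] <- Biostrings::AAStringSet(peps[slot == k])
    }
    dbs
  })
}

mutate_identity <- function(seq, identity) {
  n <- nchar(seq)
  n_mut <- round((1 - identity) * n)
  if (n_mut == 0L) return(seq)
  pos <- sample.int(n, n_mut)
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

#' Generate a TE library and NAT database, planting insertions and partners
#'
#' A family-coded transposable-element library is generated (headers carry a
#' repeat-taxonomy code such as RLG or DTA); chosen noncoding transcripts
#' receive an inserted, mutated copy (default 85 % identity) of a library
#' element. NAT-database entries are reverse complements of internal windows
#' of partner transcripts.
#'
#' @param transcripts named [Biostrings::DNAStringSet]; insertions modify it.
#' @param cfg a [synth_config()].
#' @param noncoding_ids transcript names eligible for TE insertion.
#' @param n_te number of TE insertions to plant.
#' @param te_identity identity of the inserted copy to its library element.
#' @param insert_length length (nt) of the inserted TE segment.
#' @param n_nat number of NAT partners to plant.
#' @param n_library number of library elements.
#' @return list with modified `transcripts`, `te_library` and `nat_db`
#'   (DNAStringSets; library names are `id#CODE`), and ground truth
#'   `truth_te` (id, family) and `truth_nat` (id, nat_entry).
#' @export
gen_te_nat <- function(transcripts, cfg, noncoding_ids,
                       n_te = 30L, te_identity = 0.85, insert_length = 300L,
                       n_nat = 15L, n_library = 12L) {
  stopifnot(inherits(cfg, "synth_config"))
  with_stage_seed(cfg$seed, "te_nat", {
    fams <- c(TE_FAMILY_CODES,
              sample(TE_FAMILY_CODES, max(0L, n_library - length(TE_FAMILY_CODES)),
                     replace = TRUE))[seq_len(max(n_library, 1L))]
    lib_seqs <- vapply(seq_len(n_library),
                       function(i) random_dna(sample(500:1200, 1L)), character(1))
    names(lib_seqs) <- sprintf("TE%04d#%s", seq_len(n_library),
                               fams[seq_len(n_library)])
    te_library <- Biostrings::DNAStringSet(lib_seqs)
    seqs <- as.character(transcripts)
    truth_te <- data.frame(id = character(0), family = character(0),
                           stringsAsFactors = FALSE)
    if (n_te > 0) {
      if (n_te > length(noncoding_ids)) {
        stop_config("n_te", "exceeds the number of eligible noncoding transcripts")
      }
      targets <- sample(noncoding_ids, n_te)
      for (id in targets) {
        li <- sample.int(n_library, 1L)
        el <- lib_seqs[[li]]
        seg_len <- min(insert_length, nchar(el))
        st <- sample.int(nchar(el) - seg_len + 1L, 1L)
        seg <- mutate_identity(substr(el, st, st + seg_len - 1L), te_identity)
        at <- sample.int(nchar(seqs[[id]]) - 1L, 1L)
        seqs[[id]] <- paste0(substr(seqs[[id]], 1, at), seg,
                             substr(seqs[[id]], at + 1L, nchar(seqs[[id]])))
        truth_te <- rbind(truth_te,
                          data.frame(id = id,
                                     family = sub("^.*#", "", names(lib_seqs)[li]),
                                     stringsAsFactors = FALSE))
      }
    }
    truth_nat <- data.frame(id = character(0), nat_entry = character(0),
                            stringsAsFactors = FALSE)
    nat_seqs <- character(0)
    if (n_nat > 0) {
      partners <- sample(names(transcripts), n_nat)
      for (k in seq_along(partners)) {
        id <- partners[k]
        L <- nchar(seqs[[id]])
        w <- sample(150:min(300L, L - 2L), 1L)
        st <- sample.int(L - w + 1L, 1L)
        entry <- sprintf("NAT%04d", k)
        nat_seqs[entry] <- revcomp_chr(substr(seqs[[id]], st, st + w - 1L))
        truth_nat <- rbind(truth_nat,
                           data.frame(id = id, nat_entry = entry,
                                      stringsAsFactors = FALSE))
      }
    }
    list(transcripts = Biostrings::DNAStringSet(setNames(seqs, names(transcripts))),
         te_library = te_library,
         nat_db = Biostrings::DNAStringSet(nat_seqs),
         truth_te = truth_te, truth_nat = truth_nat)
  })
}
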