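# Coding-potential assessment and the consensus lncRNA call: a transcript is
# called lncRNA only when two independent lines of evidence agree — a
# CPAT-like logistic model over sequence-intrinsic features (ORF length and
# coverage, Fickett TESTCODE, hexamer usage) gives a coding probability
# <= 0.3, and a CPC-like alignment-evidence discriminant gives a score <= -1.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame over both strands
#'
#' Scans all six frames for the longest ATG..stop ORF (stop included). Ties
#' prefer the '+' strand, then the lowest start.
#'
#' @param seq nucleotide string.
#' @return `NULL` if no ORF, else a list with `start`, `end` (0-based
#'   half-open on the reported strand), `length` (nt, a multiple of 3),
#'   `coverage` (length / transcript length) and `strand`.
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    for (f in 0:2) {
      starts <- seq.int(f + 1L, by = 3L, length.out = max(0L, (n - f) %/% 3L))
      if (length(starts) == 0L) next
      codons <- substring(s, starts, starts + 2L)
      open <- NA_integer_
      for (k in seq_along(codons)) {
        cd <- codons[k]
        if (is.na(open) && cd == "ATG") open <- starts[k]
        if (!is.na(open) && cd %in% STOP_CODONS) {
          len <- starts[k] + 3L - open
          cand <- list(start = open - 1L, end = open - 1L + len,
                       length = len, coverage = len / n, strand = strand)
          if (is.null(best) || len > best$length ||
              (len == best$length && strand == "+" && best$strand == "-") ||
              (len == best$length && strand == best$strand &&
               cand$start < best$start)) {
            best <- cand
          }
          open <- NA_integer_
        }
      }
    }
  }
  best
}

fickett_env <- new.env(parent = emptyenv())

fickett_tables <- function() {
  if (is.null(fickett_env$tab)) {
    path <- system.file("extdata", "fickett_testcode.tsv", package = "meiolnc")
    fickett_env$tab <- read.delim(path, comment.char = "#",
                                  stringsAsFactors = FALSE)
  }
  fickett_env$tab
}

fickett_lookup <- function(tab, kind, base, value) {
  rows <- tab[tab$kind == kind & tab$base == base, ]
  i <- which(value >= rows$threshold)[1]  # thresholds are descending
  list(prob = rows$prob[i], weight = rows$weight[i])
}

#' Fickett TESTCODE statistic
#'
#' For each base the position-asymmetry parameter
#' `max(c1,c2,c3) / (min(c1,c2,c3) + 1)` (counts at the three codon-frame
#' positions) and the content fraction are converted to probabilities via the
#' published lookup tables, weighted and summed over the eight terms. Refuses
#' sequences shorter than 200 nt (the pipeline's lncRNA length precondition).
#'
#' @param seq nucleotide string (case-insensitive).
#' @return the TESTCODE score (roughly in 0.2 .. 1.6; higher = more
#'   coding-like).
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 200L) stop("fickett_score requires length >= 200 nt", call. = FALSE)
  tab <- fickett_tables()
  chars <- strsplit(seq, "")[[1]]
  phase <- (seq_len(n) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(chars == b & phase == p), numeric(1))
    posval <- max(cnt) / (min(cnt) + 1)
    content <- sum(cnt) / n
    lp <- fickett_lookup(tab, "position", b, posval)
    lc <- fickett_lookup(tab, "content", b, content)
    score <- score + lp$prob * lp$weight + lc$prob * lc$weight
  }
  score
}

# In-frame hexamers (step 3) of the scoring region: the longest ORF on its
# strand, or the whole sequence in frame 0 when no ORF exists.
inframe_hexamers <- function(seq) {
  seq <- toupper(seq)
  o <- longest_orf(seq)
  region <- if (is.null(o)) {
    seq
  } else {
    s <- if (o$strand == "+") seq else revcomp_chr(seq)
    substr(s, o$start + 1L, o$end)
  }
  n <- nchar(region)
  if (n < 6L) return(character(0))
  starts <- seq.int(1L, n - 5L, by = 3L)
  substring(region, starts, starts + 5L)
}

#' Hexamer-usage frequency tables from labeled sequences
#'
#' Frequencies over all 4096 ACGT hexamers with Laplace smoothing
#' (`(count + smoothing) / (total + smoothing * 4096)`), so hexamers unseen
#' in a desk-scale training set do not produce degenerate likelihood ratios.
#'
#' @param coding_seqs,noncoding_seqs character vectors of sequences.
#' @param smoothing Laplace pseudo-count per hexamer (default 0.5).
#' @return list with `coding` and `noncoding`: named frequency vectors over
#'   all 4096 hexamers.
#' @export
hexamer_table <- function(coding_seqs, noncoding_seqs, smoothing = 0.5) {
  all_hex <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                               stringsAsFactors = FALSE),
                   1, paste, collapse = "")
  freq_of <- function(seqs) {
    hx <- unlist(lapply(seqs, inframe_hexamers))
    hx <- hx[!grepl("[^ACGT]", hx)]
    cnt <- table(factor(hx, levels = all_hex))
    setNames((as.numeric(cnt) + smoothing) /
               (sum(cnt) + smoothing * length(all_hex)), all_hex)
  }
  list(coding = freq_of(coding_seqs), noncoding = freq_of(noncoding_seqs))
}

#' Mean hexamer log-likelihood ratio
#'
#' `(1/n) * sum_i ln(F_coding(hex_i) / F_noncoding(hex_i))` over the in-frame
#' hexamers of the longest ORF (whole sequence in frame 0 if none); absent
#' hexamers receive a pseudo-frequency of 1e-8.
#'
#' @param seq nucleotide string.
#' @param coding_freq,noncoding_freq named frequency vectors (see
#'   [hexamer_table()]).
#' @return mean log-likelihood ratio in nats.
#' @export
hexamer_score <- function(seq, coding_freq, noncoding_freq) {
  hx <- inframe_hexamers(seq)
  hx <- hx[!grepl("[^ACGT]", hx)]
  if (length(hx) == 0L) return(0)
  fc <- coding_freq[hx]; fc[is.na(fc)] <- 1e-8
  fn <- noncoding_freq[hx]; fn[is.na(fn)] <- 1e-8
  mean(log(fc / fn))
}

#' Sequence-intrinsic coding features
#'
#' @param seqs named character vector (or DNAStringSet) of transcripts.
#' @param hex list from [hexamer_table()].
#' @return data.frame: transcript_id, orf_start, orf_end, orf_length,
#'   orf_coverage, fickett, hexamer.
#' @export
coding_features <- function(seqs, hex) {
  seqs <- as_named_chr(seqs)
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    o <- longest_orf(s)
    data.frame(transcript_id = id,
               orf_start = if (is.null(o)) NA_integer_ else o$start,
               orf_end = if (is.null(o)) NA_integer_ else o$end,
               orf_length = if (is.null(o)) 0L else o$length,
               orf_coverage = if (is.null(o)) 0 else o$coverage,
               fickett = fickett_score(s),
               hexamer = hexamer_score(s, hex$coding, hex$noncoding),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train the CPAT-like logistic coding-potential model
#'
#' Logistic regression `P(coding) = 1 / (1 + exp(-beta . x))` with
#' `x = (1, ln(orf_length + 1), orf_coverage, fickett, hexamer)`, fitted by
#' iteratively reweighted least squares ([stats::glm()]). On separable
#' training data the fit saturates at the iteration cap, which is expected
#' and harmless for classification.
#'
#' @param features data.frame from [coding_features()].
#' @param labels logical or 0/1 vector, TRUE/1 = coding.
#' @return list of class `cpat_model` with coefficients `beta`.
#' @export
train_cpat_model <- function(features, labels) {
  df <- data.frame(y = as.integer(labels),
                   ln_orf = log(features$orf_length + 1),
                   coverage = features$orf_coverage,
                   fickett = features$fickett,
                   hexamer = features$hexamer)
  fit <- suppressWarnings(glm(y ~ ln_orf + coverage + fickett + hexamer,
                              family = binomial(), data = df,
                              control = list(maxit = 100, epsilon = 1e-10)))
  structure(list(beta = coef(fit)), class = "cpat_model")
}

#' Coding probability under a CPAT-like model
#'
#' @param model a `cpat_model`.
#' @param features data.frame from [coding_features()].
#' @return numeric vector of coding probabilities in `[0, 1]`.
#' @export
cpat_probability <- function(model, features) {
  x <- cbind(1, log(features$orf_length + 1), features$orf_coverage,
             features$fickett, features$hexamer)
  eta <- drop(x %*% model$beta)
  1 / (1 + exp(-eta))
}

#' Alignment-evidence features for the CPC-like discriminant
#'
#' Per transcript: the maximum peptide-database bit score (scaled by the
#' significance threshold), the fraction of databases with an evidential hit
#' (E-value at most `evidence_e_max`), the frame consistency of those hits
#' (fraction agreeing with the modal frame; 1 when at most one), and the log
#' ORF coverage.
#'
#' @param ids transcript ids (row order of the result).
#' @param hits data.frame from [collect_peptide_hits()].
#' @param features data.frame from [coding_features()] (same transcripts).
#' @param n_databases number of peptide databases searched.
#' @param bit_ref bit-score scaling reference (the significance threshold).
#' @param evidence_e_max loose E-value cutoff below which a database hit
#'   counts as alignment evidence (chance best-alignments against an
#'   unrelated database do not).
#' @return data.frame: transcript_id, bit_max, db_frac, frame_consistency,
#'   log_cov, plus helper columns `n_hits` and `orf_length`.
#' @export
cpc_features <- function(ids, hits, features, n_databases, bit_ref = 90,
                         evidence_e_max = 1e-3) {
  fi <- match(ids, features$transcript_id)
  out <- data.frame(transcript_id = ids,
                    bit_max = 0, db_frac = 0, frame_consistency = 1,
                    log_cov = log(features$orf_coverage[fi] + 1e-3),
                    n_hits = 0L,
                    orf_length = features$orf_length[fi],
                    stringsAsFactors = FALSE)
  if (nrow(hits) > 0) {
    sp <- split(hits, hits$query_id)
    for (id in intersect(names(sp), ids)) {
      h <- sp[[id]]
      i <- match(id, ids)
      out$bit_max[i] <- max(h$bit_score) / bit_ref
      ev <- h[h$e_value <= evidence_e_max, , drop = FALSE]
      out$db_frac[i] <- length(unique(ev$database_name)) / n_databases
      out$n_hits[i] <- nrow(ev)
      if (nrow(ev) > 1) {
        tf <- table(ev$frame)
        out$frame_consistency[i] <- max(tf) / nrow(ev)
      }
    }
  }
  out
}

#' Train the CPC-like linear discriminant
#'
#' A transparent Fisher linear discriminant over the alignment-evidence
#' features, rescaled so the boundary-side edge of the noncoding training
#' class (its 95th percentile) maps to -1: the noncoding class sits at or
#' below the -1 decision threshold retained from the consensus rule, while
#' the sign of the boundary (0) is unchanged. Transcripts with no peptide
#' hit and no ORF >= 150 nt are additionally floored at -1, making the "no
#' evidence at all" contract hold for every input.
#'
#' @param features data.frame from [cpc_features()].
#' @param labels logical or 0/1 vector, TRUE/1 = coding.
#' @return list of class `cpc_model`.
#' @export
train_cpc_model <- function(features, labels) {
  labels <- as.logical(labels)
  cols <- c("bit_max", "db_frac", "frame_consistency", "log_cov")
  x <- as.matrix(features[, cols])
  mu_c <- colMeans(x[labels, , drop = FALSE])
  mu_n <- colMeans(x[!labels, , drop = FALSE])
  s <- (stats::cov(x[labels, , drop = FALSE]) * (sum(labels) - 1) +
        stats::cov(x[!labels, , drop = FALSE]) * (sum(!labels) - 1)) /
       (nrow(x) - 2)
  s <- s + diag(1e-6, ncol(x))
  w <- solve(s, mu_c - mu_n)
  mid <- sum(w * (mu_c + mu_n)) / 2
  d0 <- drop(x %*% w) - mid
  edge_n <- quantile(d0[!labels], 0.95, names = FALSE)
  if (edge_n >= 0) edge_n <- median(d0[!labels])  # degenerate overlap
  scale <- if (edge_n < 0) -1 / edge_n else 1
  structure(list(weights = w, midpoint = mid, scale = scale, columns = cols),
            class = "cpc_model")
}

#' CPC-like decision values
#'
#' @param model a `cpc_model`.
#' @param features data.frame from [cpc_features()].
#' @return numeric vector; values <= -1 indicate confidently noncoding.
#' @export
cpc_like_score <- function(model, features) {
  x <- as.matrix(features[, model$columns])
  d <- (drop(x %*% model$weights) - model$midpoint) * model$scale
  no_evidence <- features$n_hits == 0L & features$orf_length < 150L
  d[no_evidence] <- pmin(d[no_evidence], -1)
  d
}

#' Consensus lncRNA call
#'
#' A transcript (already unidentified by the similarity cascade, length
#' > 200 nt) is called lncRNA iff `cpat_p <= 0.3` **and** `cpc_d <= -1`
#' (both boundaries inclusive); otherwise it stays `unclassified`.
#'
#' @param cpat_p CPAT-like coding probabilities.
#' @param cpc_d CPC-like decision values.
#' @return character vector, `"lncRNA"` or `"unclassified"`.
#' @export
call_lncRNA <- function(cpat_p, cpc_d) {
  ifelse(cpat_p <= 0.3 & cpc_d <= -1, "lncRNA", "unclassified")
}

#' Flag transcripts with a significant genome hit
#'
#' Nucleotide local alignment of each transcript (both strands) against the
#' genome scaffolds; the flag is TRUE iff some scaffold hit reaches
#' `bit_min` and `e_max`. Scaffold candidates are prefiltered by shared
#' 11-mers (on either strand), which is lossless at these thresholds: a
#' bit-90 hit under the +1/-2 scheme requires ~50 aligned matches and
#' therefore an exact 11-mer.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param genome [Biostrings::DNAStringSet] of scaffolds.
#' @param scoring nucleotide scoring scheme.
#' @param bit_min,e_max thresholds (defaults 90, 1e-6).
#' @param prefilter_k k-mer prefilter size.
#' @return named logical vector per transcript.
#' @export
genome_hit <- function(transcripts, genome, scoring = scoring_nucleotide(),
                       bit_min = 90, e_max = 1e-6, prefilter_k = 11L) {
  idx <- genome_kmer_index(genome, prefilter_k)
  n_db <- length(genome)
  scaffs <- as.character(genome)
  out <- setNames(logical(length(transcripts)), names(transcripts))
  for (i in seq_along(transcripts)) {
    q <- as.character(transcripts[[i]])
    for (strand_seq in c(q, revcomp_chr(q))) {
      wins <- seed_windows(strand_seq, idx, prefilter_k)
      found <- FALSE
      for (w in wins) {
        sc <- scaffs[[w$scaffold]]
        lo <- max(1L, w$from); hi <- min(nchar(sc), w$to)
        hit <- local_align(strand_seq, substr(sc, lo, hi), scoring,
                           n_db = n_db, query_id = names(transcripts)[i],
                           target_id = w$scaffold, database_name = "genome")
        # E-value over the full search space, not the extracted window
        ka <- karlin_altschul(hit$raw_score, scoring, nchar(q),
                              nchar(sc), n_db)
        if (ka$bit_score >= bit_min && ka$e_value <= e_max) {
          out[i] <- TRUE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  out
}

# Positional k-mer index over the genome scaffolds: kmer -> rows of
# (scaffold, position).
genome_kmer_index <- function(genome, k) {
  scaffs <- as.character(genome)
  kms <- character(0); sc <- character(0); pos <- integer(0)
  for (nm in names(scaffs)) {
    s <- scaffs[[nm]]
    n <- nchar(s)
    if (n < k) next
    st <- 1:(n - k + 1L)
    kms <- c(kms, substring(s, st, st + k - 1L))
    sc <- c(sc, rep(nm, length(st)))
    pos <- c(pos, st)
  }
  list(rows = split(seq_along(kms), kms), scaffold = sc, position = pos)
}

# Seed-and-extend windows: shared k-mers between the query strand and the
# indexed genome are grouped by (scaffold, diagonal); each diagonal cluster
# yields one query-sized window (+/- margin) to align against. A local
# alignment reaching the bit-90 threshold needs ~50 identical bases under
# the +1/-2 scheme and therefore contains an exact 11-mer seed, so the
# windows cover every hit that can pass.
seed_windows <- function(strand_seq, idx, k, margin = 100L, max_windows = 10L) {
  n <- nchar(strand_seq)
  if (n < k) return(list())
  qpos <- 1:(n - k + 1L)
  qk <- substring(strand_seq, qpos, qpos + k - 1L)
  hit_rows <- idx$rows[qk]
  found <- !vapply(hit_rows, is.null, logical(1))
  if (!any(found)) return(list())
  qp <- rep(qpos[found], lengths(hit_rows[found]))
  rows <- unlist(hit_rows[found], use.names = FALSE)
  df <- data.frame(scaffold = idx$scaffold[rows],
                   diag = idx$position[rows] - qp,
                   stringsAsFactors = FALSE)
  wins <- list()
  for (s in unique(df$scaffold)) {
    d <- sort(df$diag[df$scaffold == s])
    grp <- cumsum(c(TRUE, diff(d) > 50L))
    for (g in unique(grp)) {
      dd <- d[grp == g]
      wins[[length(wins) + 1L]] <- list(scaffold = s, support = length(dd),
                                        from = min(dd) + 1L - margin,
                                        to = max(dd) + n + margin)
    }
  }
  o <- order(-vapply(wins, `[[`, numeric(1), "support"))
  wins[o][seq_len(min(length(wins), max_windows))]
}

#' Train both coding-potential models from a labeled transcript set
#'
#' Convenience wrapper: builds hexamer tables from the labeled training
#' transcripts, extracts features, and fits the CPAT-like logistic model and
#' the CPC-like discriminant (the latter using peptide hits against the
#' given databases).
#'
#' @param transcripts named [Biostrings::DNAStringSet] (training set).
#' @param labels logical vector, TRUE = coding, aligned with `transcripts`.
#' @param databases ordered list of peptide databases.
#' @param scoring peptide scoring scheme.
#' @return list of class `codepot_model` (`hex`, `cpat`, `cpc`,
#'   `n_databases`).
#' @export
train_codepot <- function(transcripts, labels, databases,
                          scoring = scoring_peptide()) {
  seqs <- as_named_chr(transcripts)
  hex <- hexamer_table(seqs[labels], seqs[!labels])
  feats <- coding_features(seqs, hex)
  cpat <- train_cpat_model(feats, labels)
  hits <- collect_peptide_hits(transcripts, databases, scoring)
  cfeats <- cpc_features(names(seqs), hits, feats, length(databases))
  cpc <- train_cpc_model(cfeats, labels)
  structure(list(hex = hex, cpat = cpat, cpc = cpc,
                 n_databases = length(databases)),
            class = "codepot_model")
}

#' Assess coding potential and call lncRNAs
#'
#' Applies a trained [train_codepot()] model to transcripts (typically the
#' unidentified ones), returning the full per-transcript assessment.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param model a `codepot_model`.
#' @param databases the same ordered peptide databases used in training.
#' @param scoring peptide scoring scheme.
#' @return data.frame: transcript_id, orf fields, fickett, hexamer, cpat_p,
#'   cpc_d, call.
#' @export
assess_transcripts <- function(transcripts, model, databases,
                               scoring = scoring_peptide()) {
  seqs <- as_named_chr(transcripts)
  feats <- coding_features(seqs, model$hex)
  hits <- collect_peptide_hits(transcripts, databases, scoring)
  cfeats <- cpc_features(names(seqs), hits, feats, model$n_databases)
  feats$cpat_p <- cpat_probability(model$cpat, feats)
  feats$cpc_d <- cpc_like_score(model$cpc, cfeats)
  feats$call <- call_lncRNA(feats$cpat_p, feats$cpc_d)
  feats
}
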