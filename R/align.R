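# Local similarity search with bit-score/E-value statistics, the ordered
# identification cascade, and collapsing of transcripts sharing an identifier.

#' Scoring schemes for local alignment
#'
#' Bundle a substitution matrix, affine gap penalties and Karlin-Altschul
#' parameters (lambda, K). Peptide mode uses BLOSUM62 with gap open 11 /
#' extend 1 and the standard gapped constants lambda = 0.267, K = 0.041;
#' nucleotide mode uses +1/-2 with gap 5/2 (lambda = 1.28, K = 0.46) or
#' +5/-4 (lambda = 0.192, K = 0.176). A gap of length L costs
#' `gap_opening + L * gap_extension`.
#'
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @return list of class `align_scoring`.
#' @export
scoring_peptide <- function(gap_opening = 11, gap_extension = 1) {
  mat <- get_blosum62()
  structure(list(matrix = mat, gap_opening = gap_opening,
                 gap_extension = gap_extension,
                 lambda = 0.267, K = 0.041, type = "peptide"),
            class = "align_scoring")
}

#' @rdname scoring_peptide
#' @param scheme nucleotide match/mismatch scheme, `"+1/-2"` or `"+5/-4"`.
#' @export
scoring_nucleotide <- function(scheme = c("+1/-2", "+5/-4"),
                               gap_opening = 5, gap_extension = 2) {
  scheme <- match.arg(scheme)
  if (scheme == "+1/-2") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
    lambda <- 1.28; K <- 0.46
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(5, -4, baseOnly = TRUE)
    lambda <- 0.192; K <- 0.176
  }
  structure(list(matrix = mat, gap_opening = gap_opening,
                 gap_extension = gap_extension,
                 lambda = lambda, K = K, type = "nucleotide"),
            class = "align_scoring")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Convert a raw alignment score to bits / an E-value
#'
#' `bit_score = (lambda * raw - ln K) / ln 2`; the E-value uses the search
#' space `m * n * n_db` (query length x target length x number of database
#' sequences): `E = m * n * n_db * 2^(-bit)`.
#'
#' @param raw_score raw Smith-Waterman score (matrix units).
#' @param scoring an [scoring_peptide()] / [scoring_nucleotide()] object.
#' @param m,n query and target lengths.
#' @param n_db number of sequences in the searched database.
#' @return named list with `bit_score` and `e_value`.
#' @export
karlin_altschul <- function(raw_score, scoring, m, n, n_db = 1) {
  bit <- (scoring$lambda * raw_score - log(scoring$K)) / log(2)
  list(bit_score = bit, e_value = as.numeric(m) * n * n_db * 2^(-bit))
}

#' Translate the six reading frames of a transcript
#'
#' Standard genetic code; stop codons become `*`, codons containing `N`
#' become `X`. Frames -1..-3 are the frames +1..+3 of the reverse complement.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @return named character vector of the six peptides
#'   (`"+1","+2","+3","-1","-2","-3"`).
#' @export
translate_six_frames <- function(seq) {
  check_dna(seq)
  code <- Biostrings::GENETIC_CODE
  fwd <- seq
  rev <- revcomp_chr(seq)
  one <- function(x, off) {
    n <- nchar(x) - off
    n <- n - n %% 3L
    if (n <= 0L) return("")
    starts <- seq.int(off + 1L, off + n, by = 3L)
    aa <- code[substring(x, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"  # codons containing N
    paste(aa, collapse = "")
  }
  c("+1" = one(fwd, 0L), "+2" = one(fwd, 1L), "+3" = one(fwd, 2L),
    "-1" = one(rev, 0L), "-2" = one(rev, 1L), "-3" = one(rev, 2L))
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment()])
#' with the given scoring scheme; the empty alignment (score 0) is allowed,
#' so the raw score is never negative. Bit score and E-value come from
#' [karlin_altschul()].
#'
#' @param query,target character sequences of the scoring scheme's alphabet.
#' @param scoring an `align_scoring` object.
#' @param n_db database-size multiplier for the E-value.
#' @param query_id,target_id,database_name identifiers carried into the hit.
#' @param frame,strand reported as-is (0 and "+" for plain alignments).
#' @return one-row data.frame: the alignment hit (query/target ids, database,
#'   raw and bit scores, E-value, 0-based half-open query/target spans, frame,
#'   strand).
#' @export
local_align <- function(query, target, scoring, n_db = 1,
                        query_id = "query", target_id = "target",
                        database_name = "db", frame = 0L, strand = "+") {
  if (nchar(query) == 0L || nchar(target) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(query, target,
                                      substitutionMatrix = scoring$matrix,
                                      gapOpening = scoring$gap_opening,
                                      gapExtension = scoring$gap_extension,
                                      type = "local")
  raw <- max(0, Biostrings::score(pa))
  ka <- karlin_altschul(raw, scoring, nchar(query), nchar(target), n_db)
  if (raw > 0) {
    qs <- Biostrings::start(Biostrings::pattern(pa)) - 1L
    qe <- Biostrings::end(Biostrings::pattern(pa))
    ts <- Biostrings::start(Biostrings::subject(pa)) - 1L
    te <- Biostrings::end(Biostrings::subject(pa))
  } else {
    qs <- qe <- ts <- te <- 0L
  }
  data.frame(query_id = query_id, target_id = target_id,
             database_name = database_name,
             raw_score = raw, bit_score = ka$bit_score, e_value = ka$e_value,
             query_start = qs, query_end = qe,
             target_start = ts, target_end = te,
             frame = as.integer(frame), strand = strand,
             stringsAsFactors = FALSE)
}

# Best nucleotide local alignment over both strands of the query.
local_align_both_strands <- function(query, target, scoring, n_db = 1, ...) {
  fwd <- local_align(query, target, scoring, n_db, strand = "+", ...)
  rev <- local_align(revcomp_chr(query), target, scoring, n_db, strand = "-", ...)
  if (rev$raw_score > fwd$raw_score) rev else fwd
}

# Index a sequence database for the k-mer prefilter: a hash from k-mer to
# the indices of the targets containing it.
prep_db_index <- function(db, k, both_strands = FALSE) {
  targets <- as.character(db)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(targets)) {
    tk <- kmers_of(targets[[i]], k)
    if (both_strands) {
      tk <- unique(c(tk, kmers_of(revcomp_chr(targets[[i]]), k)))
    }
    for (km in tk) {
      index[[km]] <- c(index[[km]], i)
    }
  }
  list(targets = targets, index = index, k = k)
}

prefilter_candidates <- function(prepped, query_kmers) {
  hit <- unlist(mget(query_kmers, envir = prepped$index, ifnotfound = list(NULL)),
                use.names = FALSE)
  sort(unique(hit))
}

# Best translated (six-frame) hit of one transcript against one (prepped)
# peptide database. Candidate targets are restricted by shared 4-mers;
# scores come from one vectorized score-only Smith-Waterman call per frame,
# and the full alignment (for the spans) is recomputed only for the winner.
best_translated_hit <- function(id, frames, prepped, db_name, scoring) {
  n_db <- length(prepped$targets)
  k <- prepped$k
  frame_codes <- c("+1" = 1L, "+2" = 2L, "+3" = 3L,
                   "-1" = -1L, "-2" = -2L, "-3" = -3L)
  best_raw <- -Inf; best_fr <- NULL; best_tid <- NULL
  for (fr in names(frames)) {
    pep <- frames[[fr]]
    if (nchar(pep) < k) next
    cand <- prefilter_candidates(prepped, kmers_of(pep, k))
    if (length(cand) == 0L) next
    raws <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(prepped$targets[cand]),
      Biostrings::AAString(pep),
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_opening,
      gapExtension = scoring$gap_extension, type = "local",
      scoreOnly = TRUE)
    raws <- pmax(0, raws)
    j <- which.max(raws)
    # ties across frames resolve to the first frame in +1..+3,-1..-3 order
    if (raws[j] > best_raw) {
      best_raw <- raws[j]
      best_fr <- fr
      best_tid <- names(prepped$targets)[cand[j]]
    }
  }
  if (is.null(best_fr)) return(NULL)
  hit <- local_align(frames[[best_fr]], prepped$targets[[best_tid]], scoring,
                     n_db = n_db, query_id = id, target_id = best_tid,
                     database_name = db_name, frame = frame_codes[[best_fr]],
                     strand = if (frame_codes[[best_fr]] > 0) "+" else "-")
  hit
}

#' Identify transcripts by a sequential translated similarity cascade
#'
#' Databases are queried in precedence order; the first database yielding a
#' hit with `bit_score >= bit_min` and `e_value <= e_max` assigns the
#' transcript's identity (best hit = maximum bit score, ties broken by
#' minimum E-value, then database order of the target). Transcripts failing
#' every database are `unidentified`.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param databases named, ordered list of [Biostrings::AAStringSet] peptide
#'   databases (highest precedence first).
#' @param scoring peptide scoring scheme ([scoring_peptide()]).
#' @param bit_min,e_max significance thresholds (defaults 90 and 1e-6).
#' @return data.frame with one row per transcript: `transcript_id`, `status`
#'   (identified/unidentified), `identifier`, `source_db`, `bit_score`,
#'   `e_value`.
#' @export
identify_transcripts <- function(transcripts, databases,
                                 scoring = scoring_peptide(),
                                 bit_min = 90, e_max = 1e-6) {
  if (length(databases) == 0L) {
    stop("configuration error: empty database list", call. = FALSE)
  }
  if (is.null(names(databases)) || any(names(databases) == "")) {
    stop("configuration error: databases must be named", call. = FALSE)
  }
  ids <- names(transcripts)
  prepped <- lapply(databases, prep_db_index, k = 4L)
  out <- data.frame(transcript_id = ids, status = "unidentified",
                    identifier = NA_character_, source_db = NA_character_,
                    bit_score = NA_real_, e_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    frames <- translate_six_frames(as.character(transcripts[[i]]))
    for (db_name in names(databases)) {
      best <- best_translated_hit(ids[i], frames, prepped[[db_name]],
                                  db_name, scoring)
      if (!is.null(best) && best$bit_score >= bit_min && best$e_value <= e_max) {
        out$status[i] <- "identified"
        out$identifier[i] <- best$target_id
        out$source_db[i] <- db_name
        out$bit_score[i] <- best$bit_score
        out$e_value[i] <- best$e_value
        break  # later databases are never consulted
      }
    }
  }
  out
}

#' Best peptide hit per database, regardless of threshold
#'
#' Feature extraction for the CPC-like discriminant: for each transcript the
#' best six-frame hit against every database (after the k-mer prefilter; a
#' transcript sharing no 4-mer with a database has no hit there).
#'
#' @inheritParams identify_transcripts
#' @return data.frame of hits (possibly zero rows per transcript).
#' @export
collect_peptide_hits <- function(transcripts, databases,
                                 scoring = scoring_peptide()) {
  rows <- list()
  prepped <- lapply(databases, prep_db_index, k = 4L)
  for (i in seq_along(transcripts)) {
    id <- names(transcripts)[i]
    frames <- translate_six_frames(as.character(transcripts[[i]]))
    for (db_name in names(databases)) {
      best <- best_translated_hit(id, frames, prepped[[db_name]],
                                  db_name, scoring)
      if (!is.null(best)) rows[[length(rows) + 1L]] <- best
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_id = character(0), target_id = character(0),
                      database_name = character(0), raw_score = numeric(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      query_start = integer(0), query_end = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      frame = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Collapse transcripts sharing a database identifier into genes
#'
#' Transcripts assigned the same (source database, identifier) pair are
#' treated as products of one locus (or close paralogs): their per-sample
#' counts are summed and the longest member becomes the representative
#' sequence. Unidentified transcripts never merge. Total reads per sample are
#' conserved.
#'
#' @param assignments data.frame from [identify_transcripts()].
#' @param counts integer matrix, transcripts x samples, rownames =
#'   transcript ids.
#' @param transcripts optional [Biostrings::DNAStringSet] used to pick the
#'   longest member as representative.
#' @return list with `genes` (data.frame: gene_id, status, identifier,
#'   source_db, n_members, representative) and `counts` (gene x sample
#'   matrix).
#' @export
collapse_by_identifier <- function(assignments, counts, transcripts = NULL) {
  if (anyDuplicated(assignments$transcript_id)) {
    stop("input error: duplicate transcript ids", call. = FALSE)
  }
  if (!all(assignments$transcript_id %in% rownames(counts))) {
    stop("input error: counts must be indexed by transcript id", call. = FALSE)
  }
  key <- ifelse(assignments$status == "identified",
                paste(assignments$source_db, assignments$identifier, sep = ":"),
                paste0("tx:", assignments$transcript_id))
  groups <- split(assignments$transcript_id, key)
  gene_ids <- character(length(groups))
  reps <- character(length(groups))
  mat <- matrix(0, nrow = length(groups), ncol = ncol(counts),
                dimnames = list(NULL, colnames(counts)))
  meta <- assignments[match(vapply(groups, `[`, character(1), 1L),
                            assignments$transcript_id),
                      c("status", "identifier", "source_db")]
  for (g in seq_along(groups)) {
    members <- groups[[g]]
    mat[g, ] <- colSums(counts[members, , drop = FALSE])
    rep_id <- if (!is.null(transcripts)) {
      members[which.max(Biostrings::width(transcripts[members]))]
    } else {
      members[1]
    }
    reps[g] <- rep_id
    gene_ids[g] <- if (meta$status[g] == "identified") {
      paste(meta$source_db[g], meta$identifier[g], sep = ":")
    } else {
      members[1]
    }
  }
  rownames(mat) <- gene_ids
  genes <- data.frame(gene_id = gene_ids, status = meta$status,
                      identifier = meta$identifier, source_db = meta$source_db,
                      n_members = lengths(groups), representative = reps,
                      stringsAsFactors = FALSE, row.names = NULL)
  o <- order(genes$gene_id)
  list(genes = genes[o, ], counts = mat[o, , drop = FALSE])
}
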