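# Small-RNA population processing: length filtering, unique/redundant
# profiling, 5'-nucleotide bias, best-stratum mapping to a mixed reference
# (genome scaffolds + transcripts), association with gene classes, and miRNA
# family assignment.

#' Length-filter raw small-RNA reads and collapse to unique sequences
#'
#' Keeps reads with lengths in `[min_len, max_len]` (defaults 20-25 nt) and
#' collapses identical sequences to one record with a multiplicity. The sum
#' of kept and dropped multiplicities equals the number of input reads.
#'
#' @param reads character vector of read sequences (may contain duplicates),
#'   or a data.frame with columns `seq` and `mult`.
#' @param min_len,max_len length window.
#' @return list with `reads` (data.frame: seq, length, mult) and `dropped`
#'   (same shape, the out-of-window records).
#' @export
filter_reads <- function(reads, min_len = 20L, max_len = 25L) {
  if (is.character(reads)) {
    t <- table(reads)
    reads <- data.frame(seq = names(t), mult = as.integer(t),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("seq", "mult") %in% names(reads)))
  agg <- stats::aggregate(mult ~ seq, data = reads, FUN = sum)
  agg$length <- nchar(agg$seq)
  keep <- agg$length >= min_len & agg$length <= max_len
  list(reads = agg[keep, c("seq", "length", "mult")],
       dropped = agg[!keep, c("seq", "length", "mult")])
}

#' Unique/redundant read counts per length
#'
#' "Unique" counts reads whose sequence occurs exactly once; "redundant"
#' counts the reads (multiplicities summed) of sequences seen more than once.
#'
#' @param reads data.frame with `seq`, `length`, `mult` (unique sequences).
#' @return data.frame: length, unique, redundant.
#' @export
redundancy_profile <- function(reads) {
  lens <- sort(unique(reads$length))
  out <- data.frame(length = lens,
                    unique = vapply(lens, function(l) {
                      sum(reads$mult[reads$length == l] == 1L)
                    }, numeric(1)),
                    redundant = vapply(lens, function(l) {
                      m <- reads$mult[reads$length == l]
                      sum(m[m > 1L])
                    }, numeric(1)))
  out
}

#' 5'-terminal nucleotide composition at a given read length
#'
#' Read-weighted (multiplicities counted) fractions of A/C/G/T at the 5'
#' terminus of reads of length `length`.
#'
#' @param reads data.frame with `seq`, `length`, `mult`.
#' @param length read length to profile (e.g. 24).
#' @return named numeric vector over A, C, G, T summing to 1.
#' @export
five_prime_bias <- function(reads, length) {
  sel <- reads[reads$length == length, ]
  if (nrow(sel) == 0L) {
    stop(sprintf("no reads of length %d", length), call. = FALSE)
  }
  first <- substr(sel$seq, 1, 1)
  tot <- sum(sel$mult)
  vapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    sum(sel$mult[first == b]) / tot
  }, numeric(1))
}

# All exact-or-k-mismatch occurrences of `read` on the forward strand of
# every reference sequence, via Biostrings::vmatchPattern.
match_positions <- function(read, reference, max_mm) {
  hits <- Biostrings::vmatchPattern(read, reference, max.mismatch = max_mm)
  rows <- list()
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (length(h) == 0L) next
    tname <- names(reference)[i]
    for (j in seq_along(h)) {
      st <- IRanges::start(h)[j]
      sub <- substr(as.character(reference[[i]]), st, st + nchar(read) - 1L)
      mm <- sum(strsplit(sub, "")[[1]] != strsplit(read, "")[[1]])
      rows[[length(rows) + 1L]] <- data.frame(target_id = tname,
                                              position = st - 1L, mismatch = mm,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(target_id = character(0), position = integer(0),
                      mismatch = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Best-stratum mapping of small RNAs to a mixed reference
#'
#' Exact-and-1-mismatch search of each unique read against both strands of
#' every reference sequence; only the minimal-mismatch stratum is kept, and
#' all co-best hits are reported (the `-v 1 --best --strata -a` contract).
#' The reference mixes genome scaffolds and transcripts so that a read whose
#' best hit lies in non-transcribed sequence is not forced onto a transcript.
#'
#' @param reads data.frame with `seq`, `length`, `mult`.
#' @param reference named [Biostrings::DNAStringSet].
#' @param ref_kind character vector aligned with `reference`: `"genome"` or
#'   `"transcript"`.
#' @param max_mm maximal mismatches (default 1).
#' @return data.frame: seq, mult, target_id, target_kind, position (0-based),
#'   strand, mismatch.
#' @export
map_srna <- function(reads, reference, ref_kind, max_mm = 1L) {
  if (length(reference) == 0L) {
    stop("configuration error: empty reference", call. = FALSE)
  }
  stopifnot(length(ref_kind) == length(reference),
            all(ref_kind %in% c("genome", "transcript")))
  kind_of <- setNames(ref_kind, names(reference))
  out <- list()
  for (i in seq_len(nrow(reads))) {
    rd <- reads$seq[i]
    fwd <- match_positions(rd, reference, max_mm)
    if (nrow(fwd) > 0) fwd$strand <- "+"
    rev <- match_positions(revcomp_chr(rd), reference, max_mm)
    if (nrow(rev) > 0) rev$strand <- "-"
    hits <- rbind(fwd, rev)
    if (nrow(hits) == 0L) next
    best <- min(hits$mismatch)
    hits <- hits[hits$mismatch == best, , drop = FALSE]
    hits$seq <- rd
    hits$mult <- reads$mult[i]
    hits$target_kind <- unname(kind_of[hits$target_id])
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0L) {
    return(data.frame(seq = character(0), mult = integer(0),
                      target_id = character(0), target_kind = character(0),
                      position = integer(0), strand = character(0),
                      mismatch = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[, c("seq", "mult", "target_id", "target_kind", "position", "strand",
          "mismatch")]
}

#' Associate mapped small RNAs with genes and gene classes
#'
#' A gene "has sRNA similarity" iff at least one best-stratum read maps to
#' the transcript itself (a genomic-only best hit does not qualify — the
#' mixed-reference rule). Also returns per-gene read support by length and
#' '+'-strand read proportions per gene class and read length.
#'
#' @param mapping data.frame from [map_srna()].
#' @param classes data.frame with `gene_id` and `coding_class` for the
#'   transcript targets.
#' @return list with `gene_support` (gene_id, length, reads), `srna_flag`
#'   (named logical over `classes$gene_id`) and `strand_by_class`
#'   (coding_class, length, plus_fraction, reads).
#' @export
associate_srna <- function(mapping, classes) {
  tx <- mapping[mapping$target_kind == "transcript", , drop = FALSE]
  flag <- setNames(classes$gene_id %in% tx$target_id, classes$gene_id)
  if (nrow(tx) > 0) {
    tx$length <- nchar(tx$seq)
    gene_support <- stats::aggregate(mult ~ target_id + length, data = tx, FUN = sum)
    names(gene_support) <- c("gene_id", "length", "reads")
    tx$coding_class <- classes$coding_class[match(tx$target_id, classes$gene_id)]
    sbc <- stats::aggregate(cbind(plus = mult * (strand == "+"), reads = mult) ~
                              coding_class + length, data = tx, FUN = sum)
    sbc$plus_fraction <- sbc$plus / sbc$reads
    strand_by_class <- sbc[, c("coding_class", "length", "plus_fraction", "reads")]
  } else {
    gene_support <- data.frame(gene_id = character(0), length = integer(0),
                               reads = numeric(0))
    strand_by_class <- data.frame(coding_class = character(0),
                                  length = integer(0),
                                  plus_fraction = numeric(0), reads = numeric(0))
  }
  list(gene_support = gene_support, srna_flag = flag,
       strand_by_class = strand_by_class)
}

#' Assign reads to miRNA families
#'
#' Each read is assigned to the family of its best match (at most one
#' mismatch) among the family representatives; reads matching two or more
#' families equally well, or matching nothing, stay unassigned. Family names
#' are the representative headers up to the first underscore or space (so
#' `miR166_1` and `miR166_2` are one family).
#'
#' @param reads data.frame with `seq`, `mult`.
#' @param families named [Biostrings::DNAStringSet] of family representatives.
#' @return list with `counts` (family, reads) and `assigned` (per-read
#'   family or NA).
#' @export
mirna_family_assign <- function(reads, families) {
  fam_of <- sub("[ _].*$", "", names(families))
  fam_seqs <- as.character(families)
  assigned <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rd <- reads$seq[i]
    best_mm <- Inf; best_fams <- character(0)
    for (k in seq_along(fam_seqs)) {
      if (nchar(fam_seqs[k]) != nchar(rd)) next
      mm <- sum(strsplit(fam_seqs[k], "")[[1]] != strsplit(rd, "")[[1]])
      if (mm > 1L) next
      if (mm < best_mm) {
        best_mm <- mm; best_fams <- fam_of[k]
      } else if (mm == best_mm) {
        best_fams <- union(best_fams, fam_of[k])
      }
    }
    if (length(best_fams) == 1L) assigned[i] <- best_fams
  }
  ok <- !is.na(assigned)
  counts <- if (any(ok)) {
    agg <- stats::aggregate(reads$mult[ok], list(family = assigned[ok]), sum)
    data.frame(family = agg$family, reads = agg$x, stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(0), reads = numeric(0))
  }
  list(counts = counts, assigned = assigned)
}
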