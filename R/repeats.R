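# TE and NAT annotation of lncRNAs by nucleotide local similarity at the
# bit >= 70, E <= 1e-6 thresholds, with repeat-taxonomy family
# classification (D* = DNA transposon, R* = retrotransposon).

te_family_of <- function(header) sub("^[^#]*#", "", sub(" .*$", "", header))

te_class_of <- function(family) {
  ifelse(is.na(family), NA_character_,
         ifelse(substr(family, 1, 1) == "D", "DNA-transposon",
                ifelse(substr(family, 1, 1) == "R", "retrotransposon",
                       NA_character_)))
}

# Best passing hits of queries against a nucleotide library (both strands),
# k-mer prefiltered. Returns best hit per query plus the long table of all
# passing hits.
library_scan <- function(queries, library, scoring, bit_min, e_max,
                         prefilter_k = 11L) {
  prepped <- prep_db_index(library, prefilter_k, both_strands = TRUE)
  libs <- prepped$targets
  n_db <- length(libs)
  best <- list(); all_pass <- list()
  for (i in seq_along(queries)) {
    q <- as.character(queries[[i]])
    qid <- names(queries)[i]
    qk <- kmers_of(q, prefilter_k)
    b <- NULL
    for (k in prefilter_candidates(prepped, qk)) {
      hit <- local_align_both_strands(q, libs[[k]], scoring, n_db = n_db,
                                      query_id = qid,
                                      target_id = names(libs)[k],
                                      database_name = "library")
      if (hit$bit_score >= bit_min && hit$e_value <= e_max) {
        all_pass[[length(all_pass) + 1L]] <- hit
        if (is.null(b) || hit$bit_score > b$bit_score) b <- hit
      }
    }
    if (!is.null(b)) best[[length(best) + 1L]] <- b
  }
  empty <- data.frame(query_id = character(0), target_id = character(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  list(best = if (length(best)) do.call(rbind, best) else empty,
       all = if (length(all_pass)) do.call(rbind, all_pass) else empty)
}

#' Annotate transposable elements in lncRNAs
#'
#' A lncRNA contains a TE iff its best library hit reaches `bit_min` (70) and
#' `e_max` (1e-6); its family is the best hit's header code (the part after
#' `#`), one family per lncRNA (ties: higher bit score, then library order).
#' All passing hits are also returned in a secondary long-format table.
#'
#' @param lncrnas named [Biostrings::DNAStringSet].
#' @param te_library named [Biostrings::DNAStringSet]; headers `id#CODE ...`.
#' @param scoring nucleotide scoring scheme.
#' @param bit_min,e_max thresholds.
#' @return list with `annotation` (data.frame: lncRNA_id, te_family,
#'   te_class, bit_score; family NA when no passing hit) and `all_hits`.
#' @export
annotate_te <- function(lncrnas, te_library, scoring = scoring_nucleotide(),
                        bit_min = 70, e_max = 1e-6) {
  scan <- library_scan(lncrnas, te_library, scoring, bit_min, e_max)
  ann <- data.frame(lncRNA_id = names(lncrnas), te_family = NA_character_,
                    te_class = NA_character_, bit_score = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(scan$best) > 0) {
    i <- match(scan$best$query_id, ann$lncRNA_id)
    ann$te_family[i] <- te_family_of(scan$best$target_id)
    ann$te_class[i] <- te_class_of(ann$te_family[i])
    ann$bit_score[i] <- scan$best$bit_score
  }
  list(annotation = ann, all_hits = scan$all)
}

#' Flag lncRNAs that are trans-natural antisense transcripts
#'
#' A lncRNA is flagged as a trans-NAT iff its best hit against the NAT
#' database reaches the same `bit_min`/`e_max` thresholds.
#'
#' @inheritParams annotate_te
#' @param nat_db named [Biostrings::DNAStringSet] of NAT reference entries.
#' @return data.frame: lncRNA_id, nat_flag, nat_entry (best entry or NA).
#' @export
annotate_nat <- function(lncrnas, nat_db, scoring = scoring_nucleotide(),
                         bit_min = 70, e_max = 1e-6) {
  out <- data.frame(lncRNA_id = names(lncrnas), nat_flag = FALSE,
                    nat_entry = NA_character_, stringsAsFactors = FALSE)
  if (length(nat_db) == 0L) return(out)
  scan <- library_scan(lncrnas, nat_db, scoring, bit_min, e_max)
  if (nrow(scan$best) > 0) {
    i <- match(scan$best$query_id, out$lncRNA_id)
    out$nat_flag[i] <- TRUE
    out$nat_entry[i] <- scan$best$target_id
  }
  out
}

#' Per-family TE counts and the DNA/retro split
#'
#' @param annotation data.frame from [annotate_te()].
#' @return list with `by_family` (family, te_class, n) and `split`
#'   (te_class, n, percent — percentages over TE-containing lncRNAs, summing
#'   to 100).
#' @export
family_summary <- function(annotation) {
  ann <- annotation[!is.na(annotation$te_family), , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(list(by_family = data.frame(family = character(0),
                                       te_class = character(0), n = integer(0)),
                split = data.frame(te_class = character(0), n = integer(0),
                                   percent = numeric(0))))
  }
  t <- table(ann$te_family)
  by_family <- data.frame(family = names(t), te_class = te_class_of(names(t)),
                          n = as.integer(t), stringsAsFactors = FALSE)
  s <- table(ann$te_class)
  split <- data.frame(te_class = names(s), n = as.integer(s),
                      percent = round_half_up(100 * as.integer(s) / nrow(ann), 2),
                      stringsAsFactors = FALSE)
  list(by_family = by_family[order(-by_family$n), ], split = split)
}
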