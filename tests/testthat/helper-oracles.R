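# Independent oracles, implemented separately from the package code paths
# they check.

# Brute-force Gotoh local alignment (affine gaps; a gap of length L costs
# gap_open + L * gap_ext, the same convention as the implementation).
oracle_sw <- function(a, b, mat, gap_open, gap_ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (horizontal)
  FF <- matrix(-Inf, n + 1, m + 1) # gap in B (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - gap_open - gap_ext)
      FF[i, j] <- max(FF[i - 1, j] - gap_ext, H[i - 1, j] - gap_open - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exhaustive six-frame ORF scan: returns the maximal ATG..stop length (nt)
# over both strands, 0 if none. Independent of the package's codon loop.
oracle_longest_orf_len <- function(seq) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  best <- 0L
  for (s in c(toupper(seq), rc(toupper(seq)))) {
    n <- nchar(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3
      if (ncod < 2) next
      st <- f + 1 + 3 * (0:(ncod - 1))
      cod <- substring(s, st, st + 2)
      atg <- which(cod == "ATG")
      stop_i <- which(cod %in% c("TAA", "TAG", "TGA"))
      for (a in atg) {
        nxt <- stop_i[stop_i > a]
        if (length(nxt)) {
          len <- (min(nxt) - a + 1L) * 3L
          if (len > best) best <- len
        }
      }
    }
  }
  best
}

# Independent Fickett TESTCODE computation with separated position/content
# parts, reading the same published tables but through its own lookup code.
oracle_fickett <- function(seq) {
  tab <- read.delim(system.file("extdata", "fickett_testcode.tsv",
                                package = "meiolnc"),
                    comment.char = "#", stringsAsFactors = FALSE)
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  pos_part <- 0; content_part <- 0
  for (b in c("A", "C", "G", "T")) {
    c1 <- sum(s[seq(1, n, 3)] == b)
    c2 <- sum(s[seq(2, n, 3)] == b)
    c3 <- sum(s[seq(3, n, 3)] == b)
    pv <- max(c1, c2, c3) / (min(c1, c2, c3) + 1)
    cv <- (c1 + c2 + c3) / n
    pr <- tab[tab$kind == "position" & tab$base == b, ]
    cr <- tab[tab$kind == "content" & tab$base == b, ]
    pi <- which(pv >= pr$threshold)[1]
    ci <- which(cv >= cr$threshold)[1]
    pos_part <- pos_part + pr$prob[pi] * pr$weight[pi]
    content_part <- content_part + cr$prob[ci] * cr$weight[ci]
  }
  list(position = pos_part, content = content_part,
       total = pos_part + content_part)
}

# Full enumeration of the conditional NB two-sided exact test.
oracle_nb_exact <- function(zA, zB, nA, nB, phi) {
  s <- zA + zB
  if (s == 0) return(1)
  y <- 0:s
  pr <- if (phi <= 0) {
    dbinom(y, s, nA / (nA + nB))
  } else {
    rA <- nA / phi; rB <- nB / phi
    v <- exp(lgamma(y + rA) - lgamma(y + 1) +
               lgamma(s - y + rB) - lgamma(s - y + 1))
    v / sum(v)
  }
  min(1, sum(pr[pr <= pr[zA + 1] * (1 + 1e-9)]))
}

# Exhaustive scan for all <= max_mm occurrences of a read over both strands
# of every reference sequence; returns only the minimal-mismatch stratum.
oracle_srna_scan <- function(read, refs, max_mm = 1L) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  L <- nchar(read)
  rows <- list()
  for (nm in names(refs)) {
    s <- refs[[nm]]
    n <- nchar(s)
    if (n < L) next
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") read else rc(read)
      pv <- strsplit(probe, "")[[1]]
      for (st in 1:(n - L + 1)) {
        w <- strsplit(substr(s, st, st + L - 1), "")[[1]]
        mm <- sum(w != pv)
        if (mm <= max_mm) {
          rows[[length(rows) + 1L]] <- data.frame(
            target_id = nm, position = st - 1L, strand = strand,
            mismatch = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(target_id = character(0), position = integer(0),
                      strand = character(0), mismatch = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[out$mismatch == min(out$mismatch), , drop = FALSE]
}

count_dinucleotides <- function(seq) {
  n <- nchar(seq)
  table(substring(seq, 1:(n - 1), 2:n))
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
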