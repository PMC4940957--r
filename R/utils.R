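# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats glm binomial coef dbinom dnbinom median optimize pnorm
#'   predict quantile rbinom rlnorm rnbinom rpois runif sd smooth.spline var
#'   rmultinom setNames p.adjust
#' @importFrom utils head read.delim write.table
NULL

# Derive a reproducible sub-stream seed from (seed, stage label). Each
# generator stage uses its own stream so adding a stage never perturbs the
# draws of another. Kept below 2^31 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587L)
}

# Evaluate `expr` under a stage-specific RNG state, restoring the caller's
# RNG afterwards.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config(field, "must be a single fraction in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(x)
}

# Validate a nucleotide string over {A,C,G,T,N}; report the first offending
# position, as the contract requires.
check_dna <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L) {
    stop(sprintf("illegal character '%s' at position %d (alphabet is A,C,G,T,N)",
                 substr(seq, bad, bad), bad), call. = FALSE)
  }
  invisible(seq)
}

#' Round half-up to a fixed number of decimals
#'
#' Unlike [base::round()] (banker's rounding), ties are always rounded away
#' from zero, the convention used throughout the accounting tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# All k-mers of a character string (k <= nchar).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# TRUE if query and target share at least one exact k-mer. For nucleotide
# both-strand searches the reverse complement of the target is also checked
# by the caller.
shares_kmer <- function(query_kmers, target, k) {
  n <- nchar(target)
  if (n < k) return(FALSE)
  any(substring(target, 1:(n - k + 1L), k:n) %in% query_kmers)
}

geomean <- function(x) exp(mean(log(x)))

# as.character that never drops names (base as.character strips them from
# character input; the Biostrings method keeps them).
as_named_chr <- function(x) {
  out <- as.character(x)
  if (is.null(names(out))) names(out) <- names(x)
  out
}
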