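# Expression quantification and inference: TPM, per-genotype detection and
# Venn partitioning, meiocyte exclusivity, a coverage-based missing-gene
# estimate, TMM normalization, the conditional negative-binomial exact test
# with a single common dispersion, FDR control, and the two-proportion test.

#' Transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / l_g) / sum_h(c_h / l_h)` per sample.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param lengths per-gene lengths (nt), aligned with rows.
#' @return TPM matrix of the same shape; columns with all-zero counts are 0.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  rate <- counts / lengths
  denom <- colSums(rate)
  denom[denom == 0] <- 1  # all-zero column stays zero
  sweep(rate, 2, denom, "/") * 1e6
}

#' Per-genotype detection
#'
#' A gene is detected in a genotype iff its unique-read counts summed across
#' that genotype's replicates reach `min_count` (default 1: maximal
#' sensitivity, consistent with the saturated-sampling design).
#'
#' @param counts genes x samples matrix.
#' @param genotypes character vector, genotype label per column.
#' @param min_count detection threshold on the per-genotype summed counts.
#' @return logical matrix genes x genotype (columns in first-appearance
#'   order).
#' @export
detect <- function(counts, genotypes, min_count = 1) {
  stopifnot(ncol(counts) == length(genotypes))
  gts <- unique(genotypes)
  out <- vapply(gts, function(g) {
    rowSums(counts[, genotypes == g, drop = FALSE]) >= min_count
  }, logical(nrow(counts)))
  dimnames(out) <- list(rownames(counts), gts)
  out
}

#' Three-set Venn partition of detection
#'
#' Assigns every gene detected anywhere to exactly one of the 7 regions of
#' the three-genotype presence/absence diagram.
#'
#' @param detection logical matrix genes x 3 genotypes.
#' @return named integer vector over the 7 regions
#'   (`a_only, b_only, c_only, ab, ac, bc, abc`, where a/b/c follow the
#'   column order), plus attribute `sets` with the column names.
#' @export
venn_partition <- function(detection) {
  stopifnot(ncol(detection) == 3)
  key <- paste0(detection[, 1] + 0L, detection[, 2] + 0L, detection[, 3] + 0L)
  regions <- c(a_only = "100", b_only = "010", c_only = "001",
               ab = "110", ac = "101", bc = "011", abc = "111")
  out <- vapply(regions, function(r) sum(key == r), integer(1))
  names(out) <- names(regions)
  attr(out, "sets") <- colnames(detection)
  out
}

#' Meiocyte exclusivity of expression
#'
#' @param meiocyte,somatic logical detection vectors over the same genes.
#' @return character vector: `meiocyte-exclusive`, `shared`, `somatic-only`,
#'   or `undetected`.
#' @export
exclusivity <- function(meiocyte, somatic) {
  stopifnot(length(meiocyte) == length(somatic))
  out <- rep("undetected", length(meiocyte))
  out[meiocyte & somatic] <- "shared"
  out[meiocyte & !somatic] <- "meiocyte-exclusive"
  out[!meiocyte & somatic] <- "somatic-only"
  out
}

#' Estimate the number of missing genes
#'
#' Chao-type coverage estimator on the pooled per-gene read totals:
#' `n0 = f1^2 / (2 * f2)` where `f1`, `f2` are the numbers of genes seen with
#' exactly one and two reads (bias-corrected form `f1*(f1-1) / (2*(f2+1))`
#' when `f2 = 0`). The 95 % CI comes from a multinomial bootstrap over the
#' observed genes. This is a documented surrogate for the saturation
#' estimator used on the original data.
#'
#' @param pooled_counts integer vector of per-gene total read counts.
#' @param n_boot bootstrap replicates (default 1000).
#' @return list with `estimate`, `ci` (length-2 vector), `f1`, `f2`.
#' @export
estimate_missing_genes <- function(pooled_counts, n_boot = 1000L) {
  chao <- function(x) {
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    if (f1 == 0) return(0)
    if (f2 == 0) return(f1 * (f1 - 1) / 2)
    f1^2 / (2 * f2)
  }
  est <- chao(pooled_counts)
  obs <- pooled_counts[pooled_counts > 0]
  total <- sum(obs)
  boots <- vapply(seq_len(n_boot), function(i) {
    chao(drop(rmultinom(1, total, obs / total)))
  }, numeric(1))
  list(estimate = est,
       ci = unname(quantile(boots, c(0.025, 0.975), type = 1)),
       f1 = sum(pooled_counts == 1), f2 = sum(pooled_counts == 2))
}

#' TMM effective-size normalization factors
#'
#' Trimmed mean of M-values against a reference column (the highest-depth
#' sample): log-ratios trimmed 30 % each side, absolute intensities trimmed
#' 5 % each side, remaining M-values combined by precision weights. The
#' returned factors are *effective relative sizes* (depth times composition),
#' normalized to geometric mean 1, so dividing counts by them puts samples on
#' a common scale.
#'
#' @param counts genes x samples matrix.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts) {
  lib <- colSums(counts)
  ref <- which.max(lib)
  comp <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    keep <- counts[, j] > 0 & counts[, ref] > 0
    yj <- counts[keep, j]; yr <- counts[keep, ref]
    if (length(yj) == 0) return(1)
    m <- log2((yj / lib[j]) / (yr / lib[ref]))
    a <- 0.5 * log2((yj / lib[j]) * (yr / lib[ref]))
    w <- (lib[j] - yj) / (lib[j] * yj) + (lib[ref] - yr) / (lib[ref] * yr)
    lm <- quantile(m, c(0.3, 0.7), type = 7)
    la <- quantile(a, c(0.05, 0.95), type = 7)
    keep2 <- m >= lm[1] & m <= lm[2] & a >= la[1] & a <= la[2]
    if (!any(keep2)) return(1)
    2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  eff <- lib / lib[ref] * comp
  f <- eff / geomean(eff)
  names(f) <- colnames(counts)
  f
}

# Conditional NB exact two-sided p-value for group sums zA, zB from nA and nB
# equal-size replicates with common dispersion phi. Conditional on
# s = zA + zB, the NB probability parameter cancels, so the distribution over
# y = 0..s depends only on the shape parameters rA = nA/phi, rB = nB/phi
# (binomial(s, nA/(nA+nB)) in the Poisson limit phi = 0). Two-sided rule:
# sum of the probabilities of all outcomes no more likely than the observed
# one (minimum-likelihood method).
exact_nb_pvalue <- function(zA, zB, nA, nB, phi) {
  s <- zA + zB
  if (s == 0) return(1)
  y <- 0:s
  if (phi <= 0) {
    logp <- dbinom(y, s, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    logp <- lgamma(y + rA) - lgamma(y + 1) + lgamma(s - y + rB) -
      lgamma(s - y + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p_obs <- logp[zA + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-10])))
}

# Conditional log-likelihood of a common dispersion phi, summed over genes:
# within each group, the replicate vector given its sum follows a
# Dirichlet-multinomial whose log-likelihood (up to phi-free terms) is
# sum_i lgamma(y_i + r) - n*lgamma(r) + lgamma(n*r) - lgamma(z + n*r).
common_disp_cll <- function(phi, pseudo, groups) {
  r <- 1 / phi
  ll <- 0
  for (g in unique(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
      sum(lgamma(n * r) - lgamma(z + n * r))
  }
  ll
}

#' Estimate the common dispersion by conditional maximum likelihood
#'
#' A single dispersion for the whole gene set (no tagwise shrinkage), the
#' smallest faithful core of the exact-test method when only two replicates
#' per genotype are available. Counts should already be on a common
#' effective library size (pseudo-counts).
#'
#' @param pseudo genes x samples matrix of equalized counts.
#' @param groups group label per column.
#' @return the CML estimate of phi (>= 0).
#' @export
estimate_common_dispersion <- function(pseudo, groups) {
  opt <- optimize(function(lphi) common_disp_cll(exp(lphi), pseudo, groups),
                  interval = c(log(1e-6), log(5)), maximum = TRUE)
  phi <- exp(opt$maximum)
  # boundary: effectively Poisson
  if (phi <= 1.5e-6) phi <- 0
  phi
}

#' Negative-binomial exact test for two-group differential expression
#'
#' The exact-test core of the common-dispersion NB framework: counts are
#' rescaled to the geometric-mean effective library size (TMM factors) and
#' rounded (pseudo-counts), the common dispersion is estimated by conditional
#' maximum likelihood, replicate counts are summed per group, and each gene
#' gets a conditional two-sided exact p-value given its total (all outcomes
#' no more likely than the observed one). `phi = 0` gives the exact binomial
#' test.
#'
#' @param counts genes x samples matrix.
#' @param groups two-level factor/character vector per column; the first
#'   level (factor order, else alphabetical) is the baseline (log2FC is
#'   second vs first), so relabeling the groups negates the fold change.
#' @param dispersion optional fixed phi; estimated by CML when `NULL`.
#' @param norm_factors optional effective-size factors; [tmm_factors()] when
#'   `NULL`.
#' @return data.frame: gene_id, log2_fold_change, p_value, dispersion.
#' @export
nb_exact_test <- function(counts, groups, dispersion = NULL,
                          norm_factors = NULL) {
  stopifnot(ncol(counts) == length(groups))
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups are required", call. = FALSE)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  pseudo <- round(sweep(counts, 2, norm_factors, "/"))
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(pseudo, groups)
  }
  a <- groups == lev[1]; b <- groups == lev[2]
  nA <- sum(a); nB <- sum(b)
  zA <- rowSums(pseudo[, a, drop = FALSE])
  zB <- rowSums(pseudo[, b, drop = FALSE])
  p <- vapply(seq_len(nrow(pseudo)), function(i) {
    exact_nb_pvalue(zA[i], zB[i], nA, nB, dispersion)
  }, numeric(1))
  lfc <- log2((zB / nB + 0.125) / (zA / nA + 0.125))
  data.frame(gene_id = rownames(counts), log2_fold_change = lfc,
             p_value = p, dispersion = dispersion,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Storey pi0 estimate by the smoother method; NA when the fit fails.
storey_pi0 <- function(p) {
  lambda <- seq(0.05, 0.95, by = 0.05)
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- tryCatch(smooth.spline(lambda, pi0_l, df = 3), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  pi0 <- predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0) return(NA_real_)
  min(pi0, 1)
}

#' FDR control by Storey q-values (BH fallback)
#'
#' Storey q-values with the smoother pi0 estimate; when the pi0 fit fails or
#' fewer than 100 p-values are supplied, falls back to Benjamini-Hochberg
#' (pi0 = 1). Genes are flagged at `q <= level`.
#'
#' @param p_values numeric vector of p-values.
#' @param level FDR level (default 0.01).
#' @return data.frame: p_value, q_value, de_flag, plus attribute `pi0`.
#' @export
fdr_control <- function(p_values, level = 0.01) {
  m <- length(p_values)
  pi0 <- if (m >= 100) storey_pi0(p_values) else NA_real_
  if (is.na(pi0)) pi0 <- 1
  o <- order(p_values)
  q <- numeric(m)
  q[o] <- pi0 * m * p_values[o] / seq_len(m)
  q[o] <- rev(cummin(rev(q[o])))
  q <- pmin(q, 1)
  out <- data.frame(p_value = p_values, q_value = q, de_flag = q <= level)
  attr(out, "pi0") <- pi0
  out
}

#' Pooled two-proportion z-test (two-tailed)
#'
#' @param x1,n1,x2,n2 successes and totals of the two samples.
#' @return list with `z`, `p_value`, `prop1`, `prop2`.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * pnorm(-abs(z)), prop1 = p1, prop2 = p2)
}
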