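# Final accounting: the coding-class/DE breakdown tree, the detection Venn
# tables, the feature x DE-status cross-tabulation with its percentage rules,
# and proportion comparisons. The same functions run on pipeline output and
# on the shipped in-paper count fixtures.

#' Percentage with the accounting rounding rule
#'
#' `100 * numerator / denominator`, rounded half-up to 2 decimals.
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @return percentage, 2 decimals.
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("undefined percentage: denominator must be > 0", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, 2)
}

#' Cross-tabulate lncRNA features by DE status and exclusivity stratum
#'
#' Builds the feature summary table from per-gene flags: three strata (all
#' lncRNAs; meiocyte-exclusive; expressed in both transcriptomes excluding
#' the exclusive ones) x feature rows (genome hit; detected in all three
#' genotypes; both; sRNA similarity; contains TE; total), each split into
#' not-DE / DE / total counts. Row percentages are taken over the feature's
#' total (DE-status cells) and over the stratum's total lncRNA count (total
#' column), the caption rule of the original table.
#'
#' @param gene_table data.frame with logical columns `genome_hit`,
#'   `three_genotypes`, `srna_similarity`, `te_flag`, `de_flag` and a column
#'   `exclusivity` (`"meiocyte-exclusive"` or `"shared"`); rows = lncRNAs.
#' @return data.frame: stratum, feature, not_de, de, total, pct_not_de,
#'   pct_de, pct_total.
#' @export
build_crosstab <- function(gene_table) {
  needed <- c("genome_hit", "three_genotypes", "srna_similarity", "te_flag",
              "de_flag", "exclusivity")
  stopifnot(all(needed %in% names(gene_table)))
  strata <- list(
    all = rep(TRUE, nrow(gene_table)),
    meiocyte_exclusive = gene_table$exclusivity == "meiocyte-exclusive",
    shared = gene_table$exclusivity == "shared"
  )
  features <- list(
    genome_hit = quote(genome_hit),
    three_genotypes = quote(three_genotypes),
    three_genotypes_and_genome_hit = quote(three_genotypes & genome_hit),
    srna_similarity = quote(srna_similarity),
    contains_te = quote(te_flag),
    total = quote(rep(TRUE, length(de_flag)))
  )
  rows <- list()
  for (s in names(strata)) {
    g <- gene_table[strata[[s]], , drop = FALSE]
    stratum_total <- nrow(g)
    for (f in names(features)) {
      sel <- eval(features[[f]], g)
      de <- sum(sel & g$de_flag)
      nde <- sum(sel & !g$de_flag)
      tot <- de + nde
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, feature = f, not_de = nde, de = de, total = tot,
        pct_not_de = if (tot > 0) percentage(nde, tot) else NA_real_,
        pct_de = if (tot > 0) percentage(de, tot) else NA_real_,
        pct_total = if (stratum_total > 0) percentage(tot, stratum_total)
                    else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cross-tab percentages from transcribed counts
#'
#' The fixture path of [build_crosstab()]: takes the count cells directly
#' (stratum, feature, not_de, de, total) and recomputes every percentage with
#' the caption rule, so printed percentages can be checked against the
#' printed counts.
#'
#' @param counts data.frame: stratum, feature, not_de, de, total.
#' @return same rows plus pct_not_de, pct_de, pct_total.
#' @export
crosstab_from_counts <- function(counts) {
  stopifnot(all(c("stratum", "feature", "not_de", "de", "total") %in%
                  names(counts)))
  if (any(counts$not_de + counts$de != counts$total)) {
    stop("count cells are inconsistent: not_de + de != total", call. = FALSE)
  }
  out <- counts
  out$pct_not_de <- percentage(counts$not_de, counts$total)
  out$pct_de <- percentage(counts$de, counts$total)
  stratum_tot <- counts$total[counts$feature == "total"]
  names(stratum_tot) <- counts$stratum[counts$feature == "total"]
  out$pct_total <- percentage(counts$total,
                              unname(stratum_tot[counts$stratum]))
  out
}

#' Coding-class breakdown of differentially expressed genes
#'
#' The accounting tree: DEGs as a share of all genes; protein-coding vs
#' non-protein-coding DEGs as shares of all DEGs; lncRNA vs unclassified as
#' shares of non-coding DEGs; and each leaf class again as a share of all
#' DEGs (the reference denominators of the original figure).
#'
#' @param gene_table data.frame with `coding_class`
#'   (protein-coding/lncRNA/unclassified) and logical `de_flag`; or pass
#'   `counts` directly.
#' @param counts optional named list/vector with `total_genes`, `deg`,
#'   `coding_deg`, `lncRNA_deg`, `unclassified_deg` (fixture path).
#' @return data.frame: node, count, denominator, percent.
#' @export
deg_breakdown <- function(gene_table = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(gene_table) || nrow(gene_table) == 0L) {
      stop("empty gene table", call. = FALSE)
    }
    de <- gene_table[gene_table$de_flag, , drop = FALSE]
    counts <- list(total_genes = nrow(gene_table), deg = nrow(de),
                   coding_deg = sum(de$coding_class == "protein-coding"),
                   lncRNA_deg = sum(de$coding_class == "lncRNA"),
                   unclassified_deg = sum(de$coding_class == "unclassified"))
  }
  counts <- as.list(counts)
  noncoding <- counts$lncRNA_deg + counts$unclassified_deg
  if (counts$deg == 0 || counts$total_genes == 0) {
    stop("empty gene table", call. = FALSE)
  }
  node <- function(name, n, d) {
    data.frame(node = name, count = n, denominator = d,
               percent = if (d > 0) percentage(n, d) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(
    node("deg_of_total", counts$deg, counts$total_genes),
    node("coding_of_deg", counts$coding_deg, counts$deg),
    node("noncoding_of_deg", noncoding, counts$deg),
    node("lncRNA_of_noncoding", counts$lncRNA_deg, noncoding),
    node("unclassified_of_noncoding", counts$unclassified_deg, noncoding),
    node("coding_of_deg_total", counts$coding_deg, counts$deg),
    node("lncRNA_of_deg_total", counts$lncRNA_deg, counts$deg),
    node("unclassified_of_deg_total", counts$unclassified_deg, counts$deg)
  )
}

#' Venn-region percentages from region counts
#'
#' @param regions named integer vector over the 7 regions (see
#'   [venn_partition()]).
#' @return data.frame: region, count, percent (of the detected-anywhere
#'   total).
#' @export
venn_percentages <- function(regions) {
  total <- sum(regions)
  data.frame(region = names(regions), count = as.integer(regions),
             percent = percentage(as.integer(regions), total),
             stringsAsFactors = FALSE)
}

#' Proportion comparisons over cross-tab cells
#'
#' Runs the pooled two-proportion z-test on each requested pair and flags
#' significance at `alpha` (default 0.01, two-tailed).
#'
#' @param pairs data.frame with columns `label`, `x1`, `n1`, `x2`, `n2`.
#' @param alpha significance threshold.
#' @return data.frame: label, prop1, prop2, z, p_value, significant.
#' @export
compare_proportions_report <- function(pairs, alpha = 0.01) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    t <- proportion_test(pairs$x1[i], pairs$n1[i], pairs$x2[i], pairs$n2[i])
    data.frame(label = pairs$label[i], prop1 = t$prop1, prop2 = t$prop2,
               z = t$z, p_value = t$p_value,
               significant = t$p_value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a shipped count fixture
#'
#' The package ships the printed count cells of the original study's
#' accounting tables as plain-text fixtures (counts only; every percentage is
#' recomputed at run time).
#'
#' @param name fixture name: `"table1"`, `"fig1"`, `"fig2_venn"` or
#'   `"fig6_te"`.
#' @return data.frame.
#' @export
read_fixture <- function(name = c("table1", "fig1", "fig2_venn", "fig6_te")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_counts.tsv"),
                      package = "meiolnc")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
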