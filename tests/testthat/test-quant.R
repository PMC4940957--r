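# Quantification and inference: TPM, detection, Venn, exclusivity, the
# missing-gene estimate, TMM, the NB exact test, FDR control and the
# proportion test.

test_that("TPM follows its formula and normalizes columns", {
  m <- matrix(c(5, 5), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(tpm(m, c(100, 100))[, 1]), c(5e5, 5e5))
  m2 <- matrix(c(10, 20), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(tpm(m2, c(100, 400))[, 1]),
               c(666666.67, 333333.33), tolerance = 1e-8)
  set.seed(1)
  m3 <- matrix(rpois(30, 50), ncol = 3)
  expect_equal(unname(colSums(tpm(m3, rpois(10, 500) + 100))), rep(1e6, 3))
})

test_that("detection thresholds act on per-genotype summed counts", {
  counts <- rbind(g1 = c(0, 0, 0, 0), g2 = c(1, 0, 0, 0), g3 = c(2, 2, 0, 0))
  gts <- c("dom", "dom", "wild", "wild")
  d <- detect(counts, gts)
  expect_false(any(d["g1", ]))
  expect_true(d["g2", "dom"])
  expect_false(d["g2", "wild"])
  d5 <- detect(counts, gts, min_count = 5)
  expect_false(d5["g3", "dom"])
})

test_that("the Venn partition is exact and conservative", {
  det <- cbind(dom = c(TRUE, TRUE, FALSE, TRUE, FALSE),
               wild = c(TRUE, FALSE, TRUE, TRUE, FALSE),
               F1 = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  v <- venn_partition(det)
  expect_equal(unname(v[c("abc", "ac", "bc", "ab")]), c(1L, 1L, 1L, 1L))
  expect_equal(sum(v), sum(rowSums(det) > 0))
  # planted region sizes recover exactly
  set.seed(6)
  regions <- c(a_only = 3L, b_only = 5L, c_only = 2L, ab = 7L, ac = 4L,
               bc = 6L, abc = 11L)
  rows <- list(a_only = c(TRUE, FALSE, FALSE), b_only = c(FALSE, TRUE, FALSE),
               c_only = c(FALSE, FALSE, TRUE), ab = c(TRUE, TRUE, FALSE),
               ac = c(TRUE, FALSE, TRUE), bc = c(FALSE, TRUE, TRUE),
               abc = c(TRUE, TRUE, TRUE))
  det2 <- do.call(rbind, rep(unlist(lapply(names(regions), function(r) {
    rep(list(rows[[r]]), regions[[r]])
  }), recursive = FALSE), 1))
  det2 <- det2[sample(nrow(det2)), ]
  colnames(det2) <- c("dom", "wild", "F1")
  expect_equal(venn_partition(det2)[names(regions)], regions,
               ignore_attr = TRUE)
})

test_that("exclusivity labels the planted pattern", {
  mei <- c(TRUE, TRUE, FALSE, FALSE)
  som <- c(FALSE, TRUE, TRUE, FALSE)
  expect_identical(exclusivity(mei, som),
                   c("meiocyte-exclusive", "shared", "somatic-only",
                     "undetected"))
})

test_that("missing-gene estimator follows the coverage formula", {
  expect_equal(estimate_missing_genes(c(3, 5, 7), n_boot = 10)$estimate, 0)
  expect_equal(estimate_missing_genes(c(1, 1, 2, 5), n_boot = 10)$estimate, 2)
  # saturated sampling: estimate 0 with a small upper bound
  set.seed(13)
  pooled <- rpois(2000, 60) + 3
  mg <- estimate_missing_genes(pooled, n_boot = 200)
  expect_equal(mg$estimate, 0)
  expect_lte(mg$ci[2], 3)
})

test_that("TMM factors are exact on constructed scalings", {
  set.seed(2)
  base <- rnbinom(2000, mu = 100, size = 10) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base, s4 = base)
  expect_equal(unname(tmm_factors(m)), rep(1, 4))
  m2 <- cbind(s1 = base, s2 = base * 2L, s3 = base, s4 = base)
  f <- tmm_factors(m2)
  expect_equal(unname(f["s2"] / f["s1"]), 2, tolerance = 0.01)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM factors approximate the standard implementation", {
  skip_if_not_installed("edgeR")
  set.seed(14)
  m <- matrix(rnbinom(4000, mu = 150, size = 5), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  m[, 2] <- m[, 2] * 3L
  ours <- tmm_factors(m)
  ed <- edgeR::calcNormFactors(m, method = "TMM") * colSums(m)
  ed <- ed / exp(mean(log(ed)))
  expect_equal(unname(ours), unname(ed), tolerance = 0.05)
})

test_that("the NB exact test matches exhaustive enumeration for s <= 30", {
  for (s in 1:30) {
    for (zA in 0:s) {
      for (phi in c(0, 0.1, 0.5)) {
        expect_equal(meiolnc:::exact_nb_pvalue(zA, s - zA, 2, 2, phi),
                     oracle_nb_exact(zA, s - zA, 2, 2, phi),
                     tolerance = 1e-12,
                     info = sprintf("s=%d zA=%d phi=%.1f", s, zA, phi))
      }
    }
  }
  # Poisson limit equals the exact binomial two-tail by enumeration
  expect_equal(meiolnc:::exact_nb_pvalue(0, 10, 2, 2, 0),
               oracle_nb_exact(0, 10, 2, 2, 0))
})

test_that("balanced counts give p = 1 and label swaps negate the log2FC", {
  m <- matrix(c(20, 22, 20, 22), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  res <- nb_exact_test(m, c("A", "A", "B", "B"), dispersion = 0.1,
                       norm_factors = rep(1, 4))
  expect_equal(res$p_value, 1)
  set.seed(3)
  m2 <- matrix(rnbinom(200 * 4, mu = 80, size = 10), ncol = 4,
               dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  ga <- c("A", "A", "B", "B")
  r1 <- nb_exact_test(m2, ga, dispersion = 0.1, norm_factors = rep(1, 4))
  r2 <- nb_exact_test(m2, rev(ga), dispersion = 0.1, norm_factors = rep(1, 4))
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$log2_fold_change, -r2$log2_fold_change)
})

test_that("common-dispersion CML recovers the simulated dispersion", {
  cfg <- synth_config(de_fraction = 0, nb_dispersion = 0.1, seed = 42L)
  gc <- gen_counts(sprintf("g%04d", 1:2000), cfg)
  sel <- gc$meta$genotype %in% c("domesticated", "wild")
  pseudo <- round(sweep(gc$counts[, sel], 2,
                        tmm_factors(gc$counts[, sel]), "/"))
  phi <- estimate_common_dispersion(pseudo, gc$meta$genotype[sel])
  expect_gt(phi, 0.07)
  expect_lt(phi, 0.14)
})

test_that("type-I error is nominal and power is adequate on planted data", {
  cfg <- synth_config(de_fraction = 0, nb_dispersion = 0.1, seed = 42L)
  gc <- gen_counts(sprintf("g%04d", 1:2000), cfg)
  sel <- gc$meta$genotype %in% c("domesticated", "wild")
  de <- nb_exact_test(gc$counts[, sel], gc$meta$genotype[sel])
  expect_gte(mean(de$p_value <= 0.05), 0.03)
  expect_lte(mean(de$p_value <= 0.05), 0.07)
  f <- fdr_control(de$p_value, 0.01)
  expect_lte(sum(f$de_flag), 2)  # ~0 false flags at FDR 1 % under the null
  # planted effects: power and realized FDR
  cfg2 <- synth_config(de_fraction = 0.1, log2_effect = 2,
                       nb_dispersion = 0.1, mean_count = 500, seed = 11L)
  gc2 <- gen_counts(sprintf("g%04d", 1:2000), cfg2)
  sel2 <- gc2$meta$genotype %in% c("domesticated", "wild")
  de2 <- nb_exact_test(gc2$counts[, sel2], gc2$meta$genotype[sel2])
  f2 <- fdr_control(de2$p_value, 0.01)
  power <- mean(f2$de_flag[gc2$truth$true_de])
  fdr <- sum(f2$de_flag & !gc2$truth$true_de) / max(1, sum(f2$de_flag))
  expect_gte(power, 0.6)
  expect_lte(fdr, 0.05)
})

test_that("q-values control the FDR with the documented fallbacks", {
  f1 <- fdr_control(rep(1, 50))
  expect_equal(sum(f1$de_flag), 0)
  # m < 100 forces the BH fallback (pi0 = 1)
  p <- c(rep(1e-4, 10), rep(1, 89))
  f2 <- fdr_control(p, 0.01)
  expect_equal(attr(f2, "pi0"), 1)
  expect_equal(sum(f2$de_flag), 10)
  expect_equal(f2$q_value[1], 99 * 1e-4 / 10)  # hand BH arithmetic
  # q monotone in ranked p
  set.seed(5)
  p3 <- runif(500)^2
  f3 <- fdr_control(p3)
  o <- order(p3)
  expect_true(all(diff(f3$q_value[o]) >= -1e-12))
})

test_that("the pooled two-proportion z-test matches its closed form", {
  t0 <- proportion_test(50, 100, 50, 100)
  expect_equal(t0$z, 0)
  expect_equal(t0$p_value, 1)
  t1 <- proportion_test(60, 100, 40, 100)
  pp <- 0.5
  se <- sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  z <- 0.2 / se
  expect_equal(t1$z, z)
  expect_equal(t1$p_value, 2 * pnorm(-z))
  t2 <- proportion_test(30, 120, 25, 100)
  expect_equal(t2$p_value, 1)  # identical proportions
})
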