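# CPM, filtering, dispersion, conditional exact test, TE GLM, BH.

test_that("CPM columns sum to 1e6 and match elementwise recomputation", {
  counts <- matrix(c(1, 1, 2), 3, 1)
  expect_equal(as.numeric(cpm_normalise(counts, 4)),
               c(250000, 250000, 500000))
  counts <- rbind(matrix(rpois(49 * 6, 40), 49, 6), 0)  # all-zero gene
  cpm <- cpm_normalise(counts)
  expect_equal(unname(colSums(cpm)), rep(1e6, 6), tolerance = 1e-9)
  expect_true(all(cpm[50, ] == 0))
  lib <- colSums(counts)
  for (j in 1:6) expect_equal(cpm[, j], counts[, j] / lib[j] * 1e6)
  expect_error(cpm_normalise(counts, c(lib[-6], 0)), "library")
})

test_that("low-expression filter uses the smallest-library CPM threshold", {
  # smallest library 2e6 -> threshold 5 / 2e6 * 1e6 = 2.5
  counts <- matrix(rpois(100 * 4, 20), 100, 4)
  lib <- c(2e6, 3e6, 4e6, 5e6)
  fl <- filter_low_expression(counts, min_samples = 2, library_sizes = lib,
                              min_count = 5)
  expect_equal(fl$cpm_threshold, 2.5)
  # boundary: gene exactly at the threshold in all samples is retained
  counts2 <- matrix(5, 1, 4)
  fl2 <- filter_low_expression(counts2, min_samples = 4,
                               library_sizes = rep(2e6, 4))
  expect_true(fl2$keep[1])
  # retained set equals the oracle applying the same rule
  set.seed(41)
  counts3 <- matrix(rnbinom(300 * 4, mu = 4, size = 2), 300, 4)
  lib3 <- c(8e5, 1e6, 1.2e6, 9e5)
  fl3 <- filter_low_expression(counts3, min_samples = 2,
                               library_sizes = lib3)
  thr <- 5 / min(lib3) * 1e6
  keep_oracle <- vapply(seq_len(300), function(g) {
    sum(counts3[g, ] / lib3 * 1e6 >= thr) >= 2
  }, logical(1))
  expect_equal(unname(fl3$keep), keep_oracle)
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  set.seed(42)
  n <- 2000
  mu <- exp(rnorm(n, log(60), 1))
  pois <- matrix(rpois(n * 8, rep(mu, 8)), n, 8)
  grp <- rep(c("a", "b"), each = 4)
  est0 <- estimate_dispersion(pois, grp)
  expect_lte(median(est0$dispersion), 0.02)
  nb <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 10), n, 8)
  est1 <- estimate_dispersion(nb, grp)
  expect_gte(median(est1$dispersion), 0.05)
  expect_lte(median(est1$dispersion), 0.2)
  # constant counts -> raw estimate floored at 0
  const <- matrix(7, 5, 8)
  estc <- estimate_dispersion(rbind(const, nb[1:100, ]), grp)
  expect_equal(estc$raw[1:5], rep(0, 5))
  expect_error(estimate_dispersion(nb[, c(1, 5)], c("a", "b")), "replicates")
})

test_that("exact test handles the symmetric and degenerate cases", {
  grp <- rep(c("control", "treatment"), each = 4)
  # identical group totals under equal libraries -> lfc 0, p 1
  counts <- matrix(5, 2, 8, dimnames = list(c("g1", "g2"), NULL))
  res <- exact_test_nb(counts, grp, 0.1, library_sizes = rep(1e6, 8))
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$pvalue, c(1, 1))
  expect_error(exact_test_nb(counts, grp, -0.5), "negative")
})

test_that("exact test agrees with the enumerated conditional binomial as phi -> 0", {
  grp <- rep(c("control", "treatment"), each = 4)
  cases <- list(c(0, 10), c(3, 7), c(12, 12), c(1, 25))
  for (cs in cases) {
    counts <- matrix(0, 1, 8, dimnames = list("g", NULL))
    counts[1, 1] <- cs[1]       # control total
    counts[1, 5] <- cs[2]       # treatment total
    res <- exact_test_nb(counts, grp, 0, library_sizes = rep(1e6, 8))
    t <- sum(cs)
    pm <- dbinom(0:t, t, 0.5)
    obs <- pm[cs[2] + 1]
    p_oracle <- sum(pm[pm <= obs * (1 + 1e-10)])
    expect_equal(res$pvalue, p_oracle, tolerance = 1e-9)
  }
})

test_that("exact test is symmetric under group exchange", {
  set.seed(43)
  n <- 50
  counts <- matrix(rnbinom(n * 8, mu = 50, size = 10), n, 8,
                   dimnames = list(paste0("g", 1:n), NULL))
  grp <- rep(c("control", "treatment"), each = 4)
  a <- exact_test_nb(counts, grp, 0.1)
  b <- exact_test_nb(counts[, c(5:8, 1:4)], grp, 0.1,
                     library_sizes = colSums(counts)[c(5:8, 1:4)])
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-9)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-9)
})

test_that("TE interaction is exactly zero when RPF is proportional to mRNA", {
  set.seed(44)
  n <- 80
  mu <- exp(rnorm(n, log(100), 1))
  m <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 10), n, 8,
              dimnames = list(paste0("g", 1:n), paste0("m", 1:8)))
  lam <- runif(8, 0.5, 2)
  r <- sweep(m, 2, lam, "*")
  colnames(r) <- paste0("r", 1:8)
  des_m <- data.frame(sample = colnames(m),
                      condition = rep(c("control", "treatment"), each = 4))
  des_r <- data.frame(sample = colnames(r),
                      condition = rep(c("control", "treatment"), each = 4))
  te <- test_differential_te(m, r, des_m, des_r)
  expect_lt(max(abs(te$log2fc)), 1e-6)
  expect_lt(max(abs(te$te_ratio)), 1e-9)
  expect_true(all(te$converged))
})

test_that("TE null p-values are approximately uniform", {
  set.seed(45)
  n <- 2000
  mu <- exp(rnorm(n, log(80), 1))
  m <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 10), n, 8,
              dimnames = list(paste0("g", 1:n), paste0("m", 1:8)))
  r <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 10), n, 8,
              dimnames = list(paste0("g", 1:n), paste0("r", 1:8)))
  des_m <- data.frame(sample = colnames(m),
                      condition = rep(c("control", "treatment"), each = 4))
  des_r <- data.frame(sample = colnames(r),
                      condition = rep(c("control", "treatment"), each = 4))
  te <- test_differential_te(m, r, des_m, des_r)
  expect_gt(stats::ks.test(te$pvalue, "punif")$p.value, 0.01)
  expect_lt(abs(mean(te$pvalue < 0.05) - 0.05), 0.025)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(46)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # order-preserving and monotone
  p <- runif(30)
  f <- bh_adjust(p)
  expect_true(all(diff(f[order(p)]) >= -1e-12))
})

test_that("significance rule combines FDR and fold-change thresholds", {
  sim <- make_small_sim(seed = 47, n_genes = 200, target_fraction = 0.3,
                        effect_model = list(s = -2, t = 0))
  des <- sim$cm$design
  sel <- des$assay == "mrna"
  res <- de_analysis(sim$cm$counts[, sel], des[sel, ], level = "mRNA")
  expect_true(all(res$significant == (res$fdr < 0.05 & abs(res$log2fc) > 0.5)))
  tgt <- sim$tx$truth$genes$gene_id[sim$tx$truth$genes$is_target]
  hit <- res$gene_id[res$significant & res$log2fc < 0]
  expect_gt(length(intersect(hit, tgt)) / length(intersect(tgt, res$gene_id)),
            0.6)
  expect_false(is.na(attr(res, "cpm_threshold")))
})
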