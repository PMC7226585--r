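# Synthetic-data generator: planted-site round trips, count moments,
# footprint phasing, Ct tables, determinism.

test_that("target_fraction = 0 yields a clean background", {
  cfg <- sim_config(n_genes = 40, target_fraction = 0, seed = 21)
  tx <- generate_transcriptome(cfg)
  expect_equal(nrow(tx$truth$sites), 0L)
  sites <- scan_genes(
    utr3 = setNames(tx$transcripts$utr3, tx$transcripts$transcript_id),
    cds = setNames(tx$transcripts$cds, tx$transcripts$transcript_id),
    mirna = cfg$mirna)
  expect_equal(nrow(sites), 0L)
  expect_true(all(tx$truth$genes$s == 0 & tx$truth$genes$t == 0))
})

test_that("every planted site is recovered exactly, per type and position", {
  cfg <- sim_config(n_genes = 200, target_fraction = 0.5, seed = 22,
                    region_probs = c(utr3 = 0.7, cds = 0.3))
  tx <- generate_transcriptome(cfg)
  sites <- scan_genes(
    utr3 = setNames(tx$transcripts$utr3, tx$transcripts$transcript_id),
    cds = setNames(tx$transcripts$cds, tx$transcripts$transcript_id),
    mirna = cfg$mirna)
  got <- sites[order(sites$gene_id, sites$region, sites$start),
               c("gene_id", "region", "start", "site_type")]
  want <- tx$truth$sites[order(tx$truth$sites$gene_id, tx$truth$sites$region,
                               tx$truth$sites$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
  # per-type counts agree with truth
  expect_identical(table(got$site_type), table(want$site_type))
  # CDS sequences keep their start and stop codons
  expect_true(all(substr(tx$transcripts$cds, 1, 3) == "AUG"))
  ends <- substr(tx$transcripts$cds, tx$transcripts$cds_len - 2,
                 tx$transcripts$cds_len)
  expect_true(all(ends %in% c("UAA", "UAG", "UGA")))
})

test_that("counts honour the planted NB moments", {
  # moment check without sequence generation: variance ~ mu + phi mu^2
  n <- 10000
  truth <- list(genes = data.frame(gene_id = paste0("g", 1:n),
                                   is_target = FALSE, s = 0, t = 0,
                                   stringsAsFactors = FALSE))
  cfg <- sim_config(n_genes = n, dispersion = 0.1, lib_size_mean = 1e6,
                    n_replicates = c(mrna = 8), seed = 23)
  cm <- simulate_counts(truth, cfg)
  grp <- cm$design$condition
  x <- cm$counts[, grp == "control", drop = FALSE]
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  sel <- m > 20
  phi_hat <- mean((v[sel] - m[sel]) / m[sel]^2)
  expect_gt(phi_hat, 0.07)
  expect_lt(phi_hat, 0.13)
  # Poisson mode
  cfg0 <- sim_config(n_genes = n, dispersion = 0, lib_size_mean = 1e6,
                     n_replicates = c(mrna = 8), seed = 23)
  cm0 <- simulate_counts(truth, cfg0)
  x0 <- cm0$counts[, cm0$design$condition == "control", drop = FALSE]
  m0 <- rowMeans(x0)
  v0 <- apply(x0, 1, var)
  sel0 <- m0 > 20
  expect_lt(abs(mean((v0[sel0] - m0[sel0]) / m0[sel0]^2)), 0.01)
})

test_that("expected fold changes follow the planted effect decomposition", {
  # s = -1, t = 0: mRNA and RPF shift together, TE flat (raw group means,
  # normalisation-free check of the generator itself)
  sim <- make_small_sim(seed = 24, n_genes = 400, target_fraction = 0.2,
                        effect_model = list(s = -1, t = 0),
                        n_replicates = c(mrna = 4, rpf = 4))
  des <- sim$cm$design
  tgt <- sim$tx$truth$genes$is_target
  raw_lfc <- function(assay) {
    tr <- des$sample[des$assay == assay & des$condition == "treatment"]
    ct <- des$sample[des$assay == assay & des$condition == "control"]
    log2((rowMeans(sim$cm$counts[, tr]) + 0.5) /
           (rowMeans(sim$cm$counts[, ct]) + 0.5))
  }
  m <- raw_lfc("mrna")
  r <- raw_lfc("rpf")
  expect_lt(abs(median(m[tgt]) + 1), 0.15)
  expect_lt(abs(median(r[tgt]) + 1), 0.15)
  expect_lt(abs(median(r[tgt] - m[tgt])), 0.15)   # TE ~ 0
  expect_lt(abs(median(m[!tgt])), 0.1)
})

test_that("footprints are phased and calibrated as configured", {
  cfg <- sim_config(n_genes = 60, seed = 25, periodicity = 1,
                    psite_offset = 12, init_peak = 0.1)
  tx <- generate_transcriptome(cfg)
  reg <- region_table(tx$transcripts)
  fp <- simulate_footprints(tx$transcripts, cfg, n_reads = 2e4)
  expect_true(all(fp$length >= 25 & fp$length <= 40))
  expect_true(all(fp$end - fp$start == fp$length))
  off <- estimate_psite_offsets(fp, reg, min_reads = 50)
  expect_true(all(off$offset == 12))
  ph <- phasing_fractions(fp, off, reg)
  expect_equal(unname(ph$frame_fractions), c(1, 0, 0))
  expect_equal(ph$dominant_frame, 0L)
  # uniform limit
  cfg3 <- sim_config(n_genes = 60, seed = 26, periodicity = 1 / 3,
                     init_peak = 0)
  tx3 <- generate_transcriptome(cfg3)
  fp3 <- simulate_footprints(tx3$transcripts, cfg3, n_reads = 1e5)
  ph3 <- phasing_fractions(fp3, 12, region_table(tx3$transcripts))
  expect_true(all(abs(ph3$frame_fractions - 1 / 3) < 0.02))
})

test_that("per-length P-site offsets are recovered per class", {
  offs <- setNames(rep(c(12, 13), c(8, 8)), as.character(25:40))
  cfg <- sim_config(n_genes = 60, seed = 27, psite_offset = offs,
                    init_peak = 0.15)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx$transcripts, cfg, n_reads = 4e4)
  est <- estimate_psite_offsets(fp, region_table(tx$transcripts),
                                min_reads = 30)
  expect_equal(est$offset[match(26, est$length)], 12)
  expect_equal(est$offset[match(39, est$length)], 13)
  expect_false(any(est$fallback))
})

test_that("Ct tables encode the planted fold changes", {
  # zero effect, zero noise -> -ddCt exactly 0
  ct0 <- simulate_ct_table(c("mirA", "mirB"), 0, noise_sd = 0, seed = 28)
  res0 <- panel_analysis(ct0)
  expect_equal(res0$neg_ddct, c(0, 0))
  expect_true(all(res0$zero_variance))
  # planted +2.78 recovered within +/-0.3 at noise 0.1, 4 replicates
  ct <- simulate_ct_table("mir96like", 2.78, noise_sd = 0.1,
                          n_replicates = 4, seed = 29)
  res <- panel_analysis(ct)
  expect_lt(abs(res$neg_ddct - 2.78), 0.3)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_genes = 30, target_fraction = 0.4, seed = 30)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a, b)
  ca <- simulate_counts(a$truth, cfg)
  cb <- simulate_counts(b$truth, cfg)
  expect_identical(ca, cb)
  fa <- simulate_footprints(a$transcripts, cfg, n_reads = 5000)
  fb <- simulate_footprints(b$transcripts, cfg, n_reads = 5000)
  expect_identical(fa, fb)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gc_content = 1.2))
  expect_error(sim_config(lib_size_mean = 0))
  expect_error(sim_config(dispersion = -1))
  expect_error(simulate_ct_table("m", 0, n_replicates = 1))
  # CDS mean forced to a multiple of 3
  cfg <- sim_config(region_lengths = c(utr5 = 100, cds = 901, utr3 = 400))
  expect_equal(unname(cfg$region_lengths["cds"] %% 3), 0)
})
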