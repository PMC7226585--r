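# Independent brute-force oracles, written as literal transcriptions of the
# definitions and kept separate from the package's optimised code paths.

# per-offset scanner oracle: tests all four patterns at every offset
# independently, then resolves overlapping classifications at one core locus
# to the strongest type (8mer > 7mer-m8 > 7mer-1a > 6mer)
oracle_find_sites <- function(seqs, mirna) {
  pat <- seed_patterns(mirna)
  types <- c("8mer", "7mer-m8", "7mer-1a", "6mer")
  plen <- c(8L, 7L, 7L, 6L)
  # core position within the site: 8mer/7mer-m8 start at m8, core is start+1
  core_shift <- c(1L, 1L, 0L, 0L)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    found <- list()
    for (ty in seq_along(types)) {
      p <- pat[[types[ty]]]
      k <- plen[ty]
      if (n < k) next
      for (o in 1:(n - k + 1L)) {
        if (substr(s, o, o + k - 1L) == p) {
          found[[length(found) + 1L]] <-
            data.frame(start = o - 1L, site_type = types[ty],
                       rank = ty, locus = o - 1L + core_shift[ty],
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(found)) next
    f <- do.call(rbind, found)
    f <- f[order(f$locus, f$rank), ]
    f <- f[!duplicated(f$locus), ]          # strongest type per core locus
    f <- f[order(f$start), ]
    out[[i]] <- data.frame(seq_index = i, start = f$start,
                           site_type = f$site_type, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(seq_index = integer(), start = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# vectorised variant of the per-offset oracle (same definition, substr
# vectorised over sequences) for large batches
oracle_find_sites_batch <- function(seqs, mirna) {
  pat <- seed_patterns(mirna)
  types <- c("8mer", "7mer-m8", "7mer-1a", "6mer")
  plen <- c(8L, 7L, 7L, 6L)
  core_shift <- c(1L, 1L, 0L, 0L)
  n <- nchar(seqs)
  hits <- list()
  for (ty in seq_along(types)) {
    p <- pat[[types[ty]]]
    k <- plen[ty]
    for (o in 1:(max(n) - k + 1L)) {
      match <- substr(seqs, o, o + k - 1L) == p & (o + k - 1L) <= n
      if (any(match)) {
        hits[[length(hits) + 1L]] <- data.frame(
          seq_index = which(match), start = o - 1L, site_type = types[ty],
          rank = ty, locus = o - 1L + core_shift[ty])
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(seq_index = integer(), start = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, hits)
  f <- f[order(f$seq_index, f$locus, f$rank), ]
  f <- f[!duplicated(f[, c("seq_index", "locus")]), ]
  f <- f[order(f$seq_index, f$start), c("seq_index", "start", "site_type")]
  f$site_type <- as.character(f$site_type)
  rownames(f) <- NULL
  f
}

# straight-line recomputation of the context-score formula for one site
oracle_score_one <- function(seq, start0, site_type, coeffs, flank = 30L) {
  len <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-1a" = 7L, "6mer" = 6L)[site_type]
  n <- nchar(seq)
  s1 <- start0 + 1L
  fl <- ""
  for (pos in seq(max(1L, s1 - flank), min(n, s1 + len - 1L + flank))) {
    if (pos < s1 || pos > s1 + len - 1L) fl <- paste0(fl, substr(seq, pos, pos))
  }
  chars <- strsplit(fl, "")[[1]]
  au <- if (length(chars)) mean(chars %in% c("A", "U")) else 0.5
  dist <- min(start0, n - (start0 + len))
  unname(coeffs$base[site_type] + coeffs$w_au * (au - 0.5) +
           coeffs$w_pos * min(dist, 1500) / 1500)
}

# literal step-up BH definition: fdr_i = min over j with p_j >= p_i of
# m * p_(j) / rank(j), computed without vectorised shortcuts
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in 1:m) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# literal transcription of the BKY (2006, Definition 6) two-stage procedure
oracle_bky <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  bh_k <- function(pv, level) {
    ps <- sort(pv)
    k <- 0
    for (i in 1:m) if (ps[i] <= level * i / m) k <- i
    k
  }
  r1 <- bh_k(p, qp)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  k2 <- bh_k(p, qp * m / m0)
  thr <- if (k2 > 0) sort(p)[k2] else -Inf
  p <= thr
}

# exhaustive-enumeration two-sample KS oracle: D over all C(n+m, n)
# relabellings of the pooled sample, p = fraction with D >= observed
oracle_ks <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  Dof <- function(xx, yy) {
    grid <- sort(unique(c(xx, yy)))
    max(abs(vapply(grid, function(g) mean(xx <= g) - mean(yy <= g),
                   numeric(1))))
  }
  d_obs <- Dof(x, y)
  combos <- utils::combn(n + m, n)
  cnt <- 0L
  for (j in seq_len(ncol(combos))) {
    xi <- combos[, j]
    if (Dof(pooled[xi], pooled[-xi]) >= d_obs - 1e-12) cnt <- cnt + 1L
  }
  list(D = d_obs, p = cnt / ncol(combos))
}

# small simulated dataset reused by several module tests
make_small_sim <- function(seed = 101, n_genes = 150, target_fraction = 0.3,
                           effect_model = list(s = -1, t = 0),
                           lib_size_mean = 2e5, ...) {
  cfg <- sim_config(n_genes = n_genes, target_fraction = target_fraction,
                    effect_model = effect_model, lib_size_mean = lib_size_mean,
                    seed = seed, ...)
  tx <- generate_transcriptome(cfg)
  cm <- simulate_counts(tx$truth, cfg)
  list(cfg = cfg, tx = tx, cm = cm)
}

# run the mRNA-level exact test on a simulated dataset
mrna_de <- function(sim) {
  des <- sim$cm$design
  sel <- des$assay == "mrna"
  m <- sim$cm$counts[, sel, drop = FALSE]
  grp <- factor(des$condition[sel], levels = c("control", "treatment"))
  disp <- estimate_dispersion(m, grp)$dispersion
  res <- exact_test_nb(m, grp, disp)
  res$level <- "mRNA"
  res
}
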