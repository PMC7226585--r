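# Synthetic-data generator: transcriptomes with planted seed sites, paired
# mRNA/RPF negative-binomial count matrices under configurable repression
# mechanisms, phased footprint alignments, and qPCR Ct tables. Defaults
# mirror the study design the package targets: quadruplicate mRNA-Seq,
# triplicate Ribo-Seq, 25-40 nt footprints with a fixed P-site offset.

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param region_lengths mean region lengths in nt, named (utr5, cds, utr3);
#'   drawn per gene around these means, CDS forced to a multiple of 3.
#' @param gc_content mean GC fraction of background sequence, in (0,1);
#'   per-gene GC varies uniformly within +/-0.12 of it (clamped to
#'   0.25-0.65), emulating real between-transcript composition spread.
#' @param n_replicates replicates per condition, named per assay
#'   (default mRNA-Seq in quadruplicate, Ribo-Seq in triplicate).
#' @param lib_size_mean expected total counts per library.
#' @param dispersion NB dispersion phi >= 0 (variance = mu + phi mu^2);
#'   0 gives Poisson counts. Default 0.1 (free parameter; per-library
#'   dispersions are not identifiable from the study design).
#' @param target_fraction fraction of genes receiving planted sites.
#' @param effect_model list with per-target log2 effects: `s` (mRNA
#'   stability, <= 0) and `t` (translational efficiency, <= 0), or
#'   `s_per_score`/`t_per_score` to make the effect proportional to the
#'   planted genes' aggregate context score (effect = scale * score, score
#'   being negative). Defaults to score-proportional destabilisation
#'   (s = 2.5 * aggregate score, t = 0), the mechanism the analysis is
#'   designed to detect.
#' @param psite_offset nt from footprint 5' end to the ribosome P site;
#'   scalar or named numeric vector by read length.
#' @param periodicity fraction of footprints whose P site falls in the
#'   canonical frame.
#' @param init_peak fraction of footprints placed with the P site exactly on
#'   the start codon (initiation pile-up; drives P-site calibration).
#' @param site_type_probs sampling probabilities for planted site types.
#' @param region_probs probability a target gene's sites are planted in the
#'   3'UTR versus the CDS.
#' @param multi_site_fraction fraction of target genes receiving multiple
#'   (2-3) sites in the same region rather than one.
#' @param pct_probs probabilities of the conserved-targeting groups
#'   (high: Pct in (0.5,1]; low: Pct in (0,0.5]; nonconserved: Pct = 0)
#'   assigned to planted targets.
#' @param mirna focal mature miRNA sequence (synthetic default).
#' @param seed RNG seed.
#' @return validated config (list of class "sim_config").
#' @export
sim_config <- function(n_genes = 1000,
                       region_lengths = c(utr5 = 100, cds = 900, utr3 = 1000),
                       gc_content = 0.45,
                       n_replicates = c(mrna = 4, rpf = 3),
                       lib_size_mean = 2e6,
                       dispersion = 0.1,
                       target_fraction = 0.25,
                       effect_model = list(s_per_score = 2.5, t_per_score = 0),
                       psite_offset = 12,
                       periodicity = 0.85,
                       init_peak = 0.1,
                       site_type_probs = c("8mer" = 0.3, "7mer-m8" = 0.35,
                                           "7mer-1a" = 0.35),
                       region_probs = c(utr3 = 0.8, cds = 0.2),
                       multi_site_fraction = 0.25,
                       pct_probs = c(high = 0.3, low = 0.4, nonconserved = 0.3),
                       mirna = "UCGGAUACGAUCGAAUGCAAGU",
                       seed = 1L) {
  stopifnot(n_genes >= 1, lib_size_mean > 0, dispersion >= 0,
            gc_content > 0, gc_content < 1,
            target_fraction >= 0, target_fraction <= 1,
            periodicity >= 0, periodicity <= 1,
            init_peak >= 0, init_peak <= 1,
            multi_site_fraction >= 0, multi_site_fraction <= 1,
            all(c("utr5", "cds", "utr3") %in% names(region_lengths)),
            all(region_lengths >= 30), all(n_replicates >= 1))
  region_lengths["cds"] <- 3 * round(region_lengths["cds"] / 3)
  cfg <- list(n_genes = as.integer(n_genes), region_lengths = region_lengths,
              gc_content = gc_content, n_replicates = n_replicates,
              lib_size_mean = lib_size_mean, dispersion = dispersion,
              target_fraction = target_fraction, effect_model = effect_model,
              psite_offset = psite_offset, periodicity = periodicity,
              init_peak = init_peak,
              site_type_probs = site_type_probs / sum(site_type_probs),
              region_probs = region_probs / sum(region_probs),
              multi_site_fraction = multi_site_fraction,
              pct_probs = pct_probs / sum(pct_probs),
              mirna = as_rna(mirna, "miRNA"), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# random background sequence with the configured GC content
random_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# background region free of the focal miRNA's 6mer core (hence of all
# canonical site types); CDS regions additionally get AUG...stop fixed.
clean_region <- function(len, gc, core, is_cds = FALSE, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    s <- random_seq(len, gc)
    if (is_cds) {
      substr(s, 1L, 3L) <- "AUG"
      substr(s, len - 2L, len) <- "UAA"
    }
    if (!length(core_starts(s, core))) return(s)
  }
  stop("failed to rejection-sample a clean background region")
}

# draw a gene's region lengths around the configured means; 3'UTR lengths
# are lognormal with a wide spread, as in real transcriptomes (real human
# 3'UTRs range from tens of nt to several kb)
draw_lengths <- function(cfg) {
  rl <- cfg$region_lengths
  u5 <- max(30L, round(stats::rnorm(1, rl["utr5"], 0.15 * rl["utr5"])))
  cds <- max(60L, 3L * round(stats::rnorm(1, rl["cds"], 0.15 * rl["cds"]) / 3))
  sdlog <- 0.6
  u3 <- max(60L, round(stats::rlnorm(1, log(rl["utr3"]) - sdlog^2 / 2, sdlog)))
  c(utr5 = u5, cds = cds, utr3 = u3)
}

# per-gene GC content around the configured mean (real transcripts vary
# widely in UTR base composition)
draw_gc <- function(cfg) {
  min(0.65, max(0.25, cfg$gc_content + stats::runif(1, -0.12, 0.12)))
}

#' Generate a synthetic transcriptome with planted miRNA sites
#'
#' Background sequence is rejection-sampled so the focal miRNA has *no*
#' chance seed matches in scanned regions (3'UTR, CDS); planted sites are
#' inserted by overwriting the region with the exact match string and then
#' re-verified, so the ground truth is exact by construction. Other miRNAs
#' may match by chance.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   * `transcripts`: data.frame (transcript_id, utr5_len, cds_len, utr3_len,
#'     utr5, cds, utr3) holding the region sequences,
#'   * `truth`: list with `genes` (gene_id, is_target, region, s, t, pct,
#'     score_sum) and `sites` (gene_id, region, start, site_type),
#'   * `config`.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    pat <- seed_patterns(cfg$mirna)
    n <- cfg$n_genes
    ids <- sprintf("gene%04d", seq_len(n))
    n_tgt <- round(cfg$target_fraction * n)
    is_target <- rep(FALSE, n)
    if (n_tgt > 0) is_target[sample.int(n, n_tgt)] <- TRUE

    tx <- vector("list", n)
    site_rows <- vector("list", n)
    for (g in seq_len(n)) {
      planted <- NULL
      if (is_target[g]) {
        region <- sample(names(cfg$region_probs), 1, prob = cfg$region_probs)
        # multi-site targets carry 2-3 sites, as typical of multi-site genes
        k <- if (stats::runif(1) < cfg$multi_site_fraction) sample(2:3, 1) else 1L
        types <- sample(names(cfg$site_type_probs), k, replace = TRUE,
                        prob = cfg$site_type_probs)
        planted <- data.frame(gene_id = ids[g], region = region,
                              start = NA_integer_, site_type = types,
                              stringsAsFactors = FALSE)
      }
      for (attempt in 1:200) {
        len <- draw_lengths(cfg)
        gc_g <- draw_gc(cfg)
        utr5 <- random_seq(len["utr5"], gc_g)
        cds <- clean_region(len["cds"], gc_g, pat$core, is_cds = TRUE)
        utr3 <- clean_region(len["utr3"], gc_g, pat$core)
        if (is.null(planted)) break
        reg_len <- unname(len[planted$region[1]])
        pat_len <- SITE_LEN[planted$site_type]
        # CDS sites avoid the first/last codon; sites must not overlap
        lo <- if (planted$region[1] == "cds") 3L else 0L
        hi <- reg_len - pat_len - (if (planted$region[1] == "cds") 3L else 0L)
        if (any(hi < lo)) {
          stop(sprintf("region %s of gene %s too short to host a site",
                       planted$region[1], ids[g]))
        }
        pos <- integer(nrow(planted))
        ok <- TRUE
        for (j in seq_len(nrow(planted))) {
          for (try_pos in 1:50) {
            p <- lo + floor(stats::runif(1) * (hi[j] - lo + 1L))
            if (j == 1L || all(abs(p - pos[seq_len(j - 1L)]) > 9L)) break
            p <- NA_integer_
          }
          if (is.na(p)) { ok <- FALSE; break }
          pos[j] <- p
        }
        if (!ok) next
        s <- if (planted$region[1] == "utr3") utr3 else cds
        for (j in seq_len(nrow(planted))) {
          substr(s, pos[j] + 1L, pos[j] + pat_len[j]) <-
            pat[[planted$site_type[j]]]
        }
        # re-verify: scanner must see exactly the planted sites (flanking
        # bases can upgrade a weaker type or spawn an extra core; reject)
        found <- find_seed_sites(s, cfg$mirna)
        o <- order(pos)
        if (nrow(found) == nrow(planted) &&
            all(found$start == pos[o]) &&
            all(found$site_type == planted$site_type[o])) {
          if (planted$region[1] == "utr3") utr3 <- s else cds <- s
          planted$start <- as.integer(pos)
          planted <- planted[o, , drop = FALSE]
          break
        }
        planted$start <- NA_integer_
        if (attempt == 200L) stop("failed to plant sites for gene ", ids[g])
      }
      tx[[g]] <- data.frame(transcript_id = ids[g], utr5_len = len[["utr5"]],
                            cds_len = len[["cds"]], utr3_len = len[["utr3"]],
                            utr5 = utr5, cds = cds, utr3 = utr3,
                            stringsAsFactors = FALSE)
      site_rows[[g]] <- planted
    }
    transcripts <- do.call(rbind, tx)
    rownames(transcripts) <- NULL
    sites <- do.call(rbind, site_rows)
    if (is.null(sites)) {
      sites <- data.frame(gene_id = character(), region = character(),
                          start = integer(), site_type = character(),
                          stringsAsFactors = FALSE)
    }
    rownames(sites) <- NULL

    # score the planted sites with the default scorer to obtain aggregate
    # context scores (used for score-proportional effect models and Pct)
    score_sum <- setNames(rep(0, n), ids)
    if (nrow(sites)) {
      utr3v <- setNames(transcripts$utr3, transcripts$transcript_id)
      cdsv <- setNames(transcripts$cds, transcripts$transcript_id)
      sc <- scan_genes(utr3 = utr3v, cds = cdsv, mirna = cfg$mirna)
      agg <- tapply(sc$context_score, sc$gene_id, sum)
      score_sum[names(agg)] <- as.numeric(agg)
    }

    em <- cfg$effect_model
    s_g <- t_g <- rep(0, n)
    if (!is.null(em$s_per_score)) {
      s_g[is_target] <- pmin(0, em$s_per_score * score_sum[is_target])
    } else if (!is.null(em$s)) s_g[is_target] <- pmin(0, em$s)
    if (!is.null(em$t_per_score)) {
      t_g[is_target] <- pmin(0, em$t_per_score * score_sum[is_target])
    } else if (!is.null(em$t)) t_g[is_target] <- pmin(0, em$t)

    pct <- rep(NA_real_, n)
    if (any(is_target)) {
      grp <- sample(names(cfg$pct_probs), sum(is_target), replace = TRUE,
                    prob = cfg$pct_probs)
      pct[is_target] <- ifelse(grp == "high", stats::runif(sum(is_target), 0.5, 1),
                        ifelse(grp == "low",
                               stats::runif(sum(is_target), 0.01, 0.5), 0))
    }
    region_of <- setNames(rep(NA_character_, n), ids)
    if (nrow(sites)) {
      region_of[unique(sites$gene_id)] <-
        sites$region[!duplicated(sites$gene_id)]
    }
    genes <- data.frame(gene_id = ids, is_target = is_target,
                        region = unname(region_of), s = s_g, t = t_g,
                        pct = pct, score_sum = unname(score_sum),
                        stringsAsFactors = FALSE)
    list(transcripts = transcripts,
         truth = list(genes = genes, sites = sites), config = cfg)
  })
}

#' Simulate paired mRNA/RPF count matrices
#'
#' Counts are NB(mu, phi) with per-condition means shifted multiplicatively:
#' the treatment mean of gene g is scaled by `2^s_g` for mRNA libraries and
#' `2^(s_g + t_g)` for RPF libraries, so the expected mRNA log2fc is s_g, the
#' expected RPF log2fc is s_g + t_g, and the expected TE log2fc is t_g by
#' construction.
#'
#' @param truth the `truth` element of [generate_transcriptome()] output (or
#'   any list with a `genes` data.frame carrying gene_id, s, t).
#' @param config a [sim_config()].
#' @param seed optional RNG seed overriding `config$seed + 1`.
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   (sample, condition, assay), `library_sizes` (drawn targets; realised
#'   column sums differ by sampling noise).
#' @export
simulate_counts <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- truth$genes
  n <- nrow(genes)
  if (is.null(seed)) seed <- cfg$seed + 1L
  with_seed(seed, {
    design <- do.call(rbind, lapply(names(cfg$n_replicates), function(a) {
      do.call(rbind, lapply(c("control", "treatment"), function(cond) {
        data.frame(sample = sprintf("%s_%s_%d", a, cond,
                                    seq_len(cfg$n_replicates[[a]])),
                   condition = cond, assay = a, stringsAsFactors = FALSE)
      }))
    }))
    m <- nrow(design)
    lib <- round(stats::rnorm(m, cfg$lib_size_mean, 0.05 * cfg$lib_size_mean))
    lib <- pmax(lib, 1)
    w <- stats::rlnorm(n, 0, 1)
    p <- w / sum(w)
    fac <- matrix(1, n, m)
    treat <- design$condition == "treatment"
    fac[, treat & design$assay == "mrna"] <- 2^genes$s
    fac[, treat & design$assay == "rpf"] <- 2^(genes$s + genes$t)
    mu <- outer(p, lib) * fac
    counts <- if (cfg$dispersion > 0) {
      matrix(stats::rnbinom(n * m, mu = mu, size = 1 / cfg$dispersion), n, m)
    } else {
      matrix(stats::rpois(n * m, lambda = mu), n, m)
    }
    dimnames(counts) <- list(genes$gene_id, design$sample)
    list(counts = counts, design = design, library_sizes = setNames(lib, design$sample))
  })
}

#' Simulate ribosome footprint alignments in transcript coordinates
#'
#' Footprint lengths are uniform on 25-40 nt. With probability `init_peak`
#' the P site is placed exactly on the start codon; otherwise it falls on an
#' interior CDS codon, in the canonical frame with probability `periodicity`
#' and uniformly off-frame otherwise. The 5' end is the P site minus the
#' (length-specific) offset, so downstream calibration can recover the
#' planted offsets exactly.
#'
#' @param transcripts transcript table from [generate_transcriptome()].
#' @param config a [sim_config()].
#' @param n_reads number of footprints.
#' @param seed optional seed (default `config$seed + 2`).
#' @return data.frame (transcript_id, start, end, length); `start` is the
#'   0-based 5'-end transcript coordinate, `end` = start + length.
#' @export
simulate_footprints <- function(transcripts, config, n_reads = 1e5,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (is.null(seed)) seed <- cfg$seed + 2L
  with_seed(seed, {
    lens_avail <- 25:40
    off <- cfg$psite_offset
    offset_of <- function(l) {
      if (length(off) == 1L && is.null(names(off))) rep(off, length(l))
      else {
        o <- off[as.character(l)]
        if (any(is.na(o))) stop("psite_offset missing for some read length")
        as.numeric(o)
      }
    }
    ti <- sample.int(nrow(transcripts), n_reads, replace = TRUE,
                     prob = transcripts$cds_len)
    len <- sample(lens_avail, n_reads, replace = TRUE)
    offs <- offset_of(len)
    u5 <- transcripts$utr5_len[ti]
    ncodon <- transcripts$cds_len[ti] %/% 3L
    at_init <- stats::runif(n_reads) < cfg$init_peak
    inframe <- stats::runif(n_reads) < cfg$periodicity
    # interior codon index 1..ncodon-2 (first and last codon reserved)
    k <- 1L + floor(stats::runif(n_reads) * (ncodon - 2L))
    sub <- ifelse(inframe, 0L, sample(1:2, n_reads, replace = TRUE))
    psite <- ifelse(at_init, u5, u5 + 3L * k + sub)
    start <- psite - round(offs)
    keep <- start >= 0
    data.frame(transcript_id = transcripts$transcript_id[ti][keep],
               start = as.integer(start[keep]),
               end = as.integer(start[keep] + len[keep]),
               length = as.integer(len[keep]), stringsAsFactors = FALSE)
  })
}

#' Simulate a qPCR Ct table
#'
#' Target Ct in the treatment condition is `baseline - true_log2fc` plus
#' Gaussian noise (one qPCR cycle = one log2 unit); reference small RNAs are
#' constant across conditions up to noise.
#'
#' @param panel character vector of miRNA names.
#' @param true_log2fc numeric vector (recycled) of planted log2 fold changes.
#' @param refs reference small RNA names (default U6, U44).
#' @param n_replicates biological replicates per condition (>= 2).
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param baseline_ct baseline target Ct.
#' @param ref_ct baseline Ct per reference (recycled).
#' @param seed RNG seed.
#' @return data.frame (mirna, sample, condition, replicate, ct).
#' @export
simulate_ct_table <- function(panel, true_log2fc = 0, refs = c("U6", "U44"),
                              n_replicates = 4, noise_sd = 0.1,
                              baseline_ct = 25, ref_ct = c(20, 22),
                              seed = 1L) {
  stopifnot(n_replicates >= 2)
  lfc <- rep_len(true_log2fc, length(panel))
  refbase <- rep_len(ref_ct, length(refs))
  with_seed(seed, {
    rows <- list()
    for (cond in c("control", "treatment")) {
      for (r in seq_len(n_replicates)) {
        smp <- sprintf("%s_%d", cond, r)
        ct_t <- baseline_ct - (cond == "treatment") * lfc +
          stats::rnorm(length(panel), 0, noise_sd)
        ct_r <- refbase + stats::rnorm(length(refs), 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = c(panel, refs), sample = smp, condition = cond,
          replicate = r, ct = c(ct_t, ct_r), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Region table for a transcript set
#' @param transcripts transcript table from [generate_transcriptome()].
#' @return data.frame (transcript_id, utr5_len, cds_len, utr3_len).
#' @export
region_table <- function(transcripts) {
  transcripts[, c("transcript_id", "utr5_len", "cds_len", "utr3_len")]
}
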