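# qPCR panel analysis for miRNA families: delta-Ct against a geometric-mean
# small-RNA reference, -ddCt fold changes, Student's t-tests, and the
# Benjamini-Krieger-Yekutieli two-stage linear step-up FDR. The reference is
# aggregated as the arithmetic mean of the reference Ct values, which equals
# the geometric mean of the reference expression levels (one qPCR cycle is
# one log2 unit).

#' Delta-Ct per miRNA and sample
#'
#' Technical replicates (rows sharing mirna and sample) are averaged first;
#' then `dCt = mean target Ct - arithmetic mean of the reference Cts` of the
#' same sample.
#'
#' @param ct_table data.frame (mirna, sample, condition, replicate, ct).
#' @param refs reference small RNA names (default U6, U44).
#' @return data.frame (mirna, sample, condition, dct), references excluded.
#' @export
delta_ct <- function(ct_table, refs = c("U6", "U44")) {
  stopifnot(all(c("mirna", "sample", "condition", "ct") %in% names(ct_table)),
            all(ct_table$ct > 0))
  key <- paste(ct_table$mirna, ct_table$sample, sep = "\r")
  agg <- tapply(ct_table$ct, key, mean)
  info <- ct_table[!duplicated(key), c("mirna", "sample", "condition")]
  info$ct <- as.numeric(agg[paste(info$mirna, info$sample, sep = "\r")])
  samples <- unique(info$sample)
  ref_mean <- vapply(samples, function(s) {
    r <- info$ct[info$sample == s & info$mirna %in% refs]
    if (length(r) != length(refs)) {
      stop("missing reference measurement in sample ", s)
    }
    mean(r)
  }, numeric(1))
  tgt <- info[!info$mirna %in% refs, , drop = FALSE]
  tgt$dct <- tgt$ct - ref_mean[tgt$sample]
  rownames(tgt) <- NULL
  tgt[, c("mirna", "sample", "condition", "dct")]
}

#' -ddCt estimate and t-test for one miRNA
#'
#' `neg_ddct = -(mean dCt_treatment - mean dCt_control)`, the estimated log2
#' fold change (positive = upregulated in treatment). The p-value is a
#' two-sided two-sample Student's t-test on the dCt values (equal-variance
#' by default; Welch by flag). Zero-variance degenerate inputs are reported
#' with p = 1 and a flag rather than failing.
#'
#' @param dct_treatment,dct_control numeric dCt vectors (>= 2 each).
#' @param var_equal equal-variance t-test (default TRUE).
#' @return list (neg_ddct, t_p, zero_variance).
#' @export
ddct_test <- function(dct_treatment, dct_control, var_equal = TRUE) {
  if (length(dct_treatment) < 2 || length(dct_control) < 2) {
    stop("need >= 2 biological replicates per condition")
  }
  nd <- -(mean(dct_treatment) - mean(dct_control))
  if (stats::sd(dct_treatment) == 0 && stats::sd(dct_control) == 0) {
    return(list(neg_ddct = nd, t_p = 1, zero_variance = TRUE))
  }
  tt <- stats::t.test(dct_treatment, dct_control, var.equal = var_equal)
  list(neg_ddct = nd, t_p = tt$p.value, zero_variance = FALSE)
}

#' Benjamini-Krieger-Yekutieli two-stage step-up FDR
#'
#' Stage 1: BH at level `q' = q / (1 + q)`; the number of rejections r1
#' estimates the number of true nulls as `m0 = m - r1` (all hypotheses
#' rejected if m0 = 0). Stage 2: BH at level `q' * m / m0`. Returns
#' significance flags in input order; as an extension (the native output of
#' the procedure is the reject/accept decision), stage-2 BH-adjusted
#' p-values rescaled so that `adjusted <= q` is exactly equivalent to the
#' flag are also returned.
#'
#' @param pvalues numeric vector in [0,1].
#' @param q target FDR (default 0.05).
#' @return list (significant: logical flags, m0, adjusted: rescaled stage-2
#'   adjusted p-values, capped at 1; `adjusted <= q` iff `significant`
#'   whenever the cap is not hit).
#' @export
bky_adjust <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  bh_reject <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    pass <- p[o] <= thr
    k <- if (any(pass)) max(which(pass)) else 0L
    rej <- logical(m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  r1 <- sum(bh_reject(pvalues, q1))
  m0 <- m - r1
  if (m0 == 0L) {
    return(list(significant = rep(TRUE, m), m0 = 0L,
                adjusted = rep(0, m)))
  }
  sig <- bh_reject(pvalues, q1 * m / m0)
  adjusted <- bh_adjust(pvalues) * (m0 / m) * (1 + q)
  list(significant = sig, m0 = m0, adjusted = pmin(1, adjusted))
}

#' Full qPCR panel analysis
#'
#' delta-Ct, per-miRNA -ddCt and t-test, and BKY two-stage FDR flags.
#'
#' @param ct_table data.frame (mirna, sample, condition, replicate, ct) with
#'   conditions "control" and "treatment".
#' @param refs reference small RNA names.
#' @param q target FDR for the BKY procedure.
#' @param var_equal equal-variance t-test (default) or Welch.
#' @return data.frame (mirna, neg_ddct, t_p, bky_significant, bky_adjusted,
#'   zero_variance).
#' @export
panel_analysis <- function(ct_table, refs = c("U6", "U44"), q = 0.05,
                           var_equal = TRUE) {
  dct <- delta_ct(ct_table, refs = refs)
  mirnas <- unique(dct$mirna)
  res <- do.call(rbind, lapply(mirnas, function(mi) {
    tr <- dct$dct[dct$mirna == mi & dct$condition == "treatment"]
    ct <- dct$dct[dct$mirna == mi & dct$condition == "control"]
    dd <- ddct_test(tr, ct, var_equal = var_equal)
    data.frame(mirna = mi, neg_ddct = dd$neg_ddct, t_p = dd$t_p,
               zero_variance = dd$zero_variance, stringsAsFactors = FALSE)
  }))
  bky <- bky_adjust(res$t_p, q = q)
  res$bky_significant <- bky$significant
  res$bky_adjusted <- bky$adjusted
  res[, c("mirna", "neg_ddct", "t_p", "bky_significant", "bky_adjusted",
          "zero_variance")]
}

#' Seed-sharing families among mature miRNAs
#'
#' Groups miRNAs by exact identity of the seed heptamer (nucleotides 2-8)
#' and additionally reports pairs whose seeds differ at a single position
#' ("similar" seeds, Hamming distance 1). Sequences shorter than 8 nt are
#' skipped with a warning.
#'
#' @param mirnas named character vector of mature sequences (or a FASTA path).
#' @return list with `families` (data.frame: mirna, seed, family) and
#'   `similar` (data.frame: mirna_a, mirna_b, distance).
#' @export
seed_family <- function(mirnas) {
  if (length(mirnas) == 1L && is.null(names(mirnas)) && file.exists(mirnas)) {
    mirnas <- read_fasta(mirnas)
  }
  if (is.null(names(mirnas))) names(mirnas) <- paste0("mir", seq_along(mirnas))
  seqs <- as_rna(mirnas, "miRNA")
  short <- nchar(seqs) < 8L
  if (any(short)) {
    warning("skipping sequences shorter than 8 nt: ",
            paste(names(seqs)[short], collapse = ", "))
    seqs <- seqs[!short]
  }
  seed <- substr(seqs, 2L, 8L)
  fam <- match(seed, unique(seed))
  families <- data.frame(mirna = names(seqs), seed = seed,
                         family = paste0("family", fam),
                         stringsAsFactors = FALSE)
  rownames(families) <- NULL
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  pairs <- list()
  if (length(seqs) > 1) {
    idx <- utils::combn(length(seqs), 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      d <- hamming(seed[i], seed[j])
      if (d == 1L) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          mirna_a = names(seqs)[i], mirna_b = names(seqs)[j], distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  similar <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(mirna_a = character(), mirna_b = character(),
               distance = integer(), stringsAsFactors = FALSE)
  list(families = families, similar = similar)
}
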