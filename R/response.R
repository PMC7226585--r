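# Target-stratified distribution-shift analysis: the core inference. Fold
# change distributions of target strata are compared against the expressed
# no-site background with the two-sided two-sample Kolmogorov-Smirnov test;
# median shifts carry percentile-bootstrap 95% CIs; within-stratum Pearson
# correlation of mRNA vs RPF fold changes quantifies the coupling between
# abundance and translation; a simple decision rule turns the three median
# shifts into a mechanism call.

# exact two-sample KS p-value by lattice-path enumeration (valid without
# ties): all C(n+m, n) interleavings are equally likely under the null, and
# an interleaving attains D >= d iff its lattice path leaves the band
# |i*m - j*n| <= d*n*m - 1. The DP propagates path *probabilities* of the
# equivalent hypergeometric walk, which keeps every quantity in [0,1] and
# avoids the overflow of raw path counts for unbalanced n, m.
ks_exact_p <- function(d, n, m) {
  lim <- round(d * n * m) - 1L   # strict bound: paths with max < observed D
  if (lim < 0L) return(1)
  u <- numeric(m + 1L)           # u[j+1] = P(reach (i,j) staying in band)
  u[1L] <- 1
  for (j in 1:m) {
    u[j + 1L] <- if (j * n <= lim) u[j] * (m - (j - 1)) / (n + m - (j - 1)) else 0
  }
  for (i in 1:n) {
    v <- numeric(m + 1L)
    v[1L] <- if (i * m <= lim) u[1L] * (n - (i - 1)) / (n + m - (i - 1)) else 0
    for (j in 1:m) {
      if (abs(i * m - j * n) <= lim) {
        v[j + 1L] <- v[j] * (m - (j - 1)) / (n + m - i - (j - 1)) +
          u[j + 1L] * (n - (i - 1)) / (n + m - (i - 1) - j)
      }
    }
    u <- v
  }
  min(1, max(0, 1 - u[m + 1L]))
}

# asymptotic two-sided two-sample KS p (Stephens' small-sample adjustment)
ks_asymp_p <- function(d, n, m) {
  ne <- n * m / (n + m)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov shift test
#'
#' D is the supremum of the absolute ECDF difference. The p-value is exact
#' (lattice-path enumeration, valid in the absence of ties) when
#' `min(n, m) <= exact_limit`, otherwise the asymptotic two-sample formula.
#'
#' @param x,y numeric vectors (stratum and background fold changes).
#' @param exact_limit use the exact p when min(n, m) is at most this
#'   (default 10).
#' @return list (D, p, n, m, method).
#' @export
ks_shift_test <- function(x, y, exact_limit = 10L) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n <- length(x)
  m <- length(y)
  if (!n || !m) stop("empty vector in KS test")
  z <- c(x, y)
  o <- order(z)
  steps <- ifelse(o <= n, 1 / n, -1 / m)
  cum <- cumsum(steps)
  # at tied values only the ECDF difference after processing the whole tie
  # block is attained
  zs <- z[o]
  last_of_block <- c(zs[-1] != zs[-length(zs)], TRUE)
  d <- max(abs(cum[last_of_block]))
  method <- if (min(n, m) <= exact_limit) "exact" else "asymptotic"
  p <- if (method == "exact") ks_exact_p(d, n, m) else ks_asymp_p(d, n, m)
  list(D = d, p = p, n = n, m = m, method = method)
}

#' Median with a percentile-bootstrap 95% CI
#'
#' @param x numeric vector (n >= 1); with n < 3 the CI degenerates to the
#'   median and is flagged.
#' @param n_boot bootstrap replicates (default 2000).
#' @param conf confidence level.
#' @param seed RNG seed (evaluated locally; the caller's RNG is untouched).
#' @return list (median, lo, hi, degenerate).
#' @export
median_with_ci <- function(x, n_boot = 2000L, conf = 0.95, seed = 1L) {
  x <- x[is.finite(x)]
  med <- stats::median(x)
  if (length(x) < 3L) {
    return(list(median = med, lo = med, hi = med, degenerate = TRUE))
  }
  qs <- with_seed(seed, {
    boots <- matrix(sample(x, length(x) * n_boot, replace = TRUE),
                    nrow = n_boot)
    bm <- apply(boots, 1, stats::median)
    stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  list(median = med, lo = qs[1], hi = qs[2], degenerate = FALSE)
}

#' Stratified distribution-shift analysis
#'
#' For each stratum of a labelling scheme and each expression level, tests
#' the stratum's log2 fold changes against the expressed no-site background
#' (two-sided KS), reports the median shift with a bootstrap 95% CI, and the
#' within-stratum Pearson correlation between mRNA and RPF fold changes.
#' Strata smaller than `min_genes` are reported descriptively with NA
#' statistics. BH-adjusted KS p-values across strata are added per level
#' (raw p-values are kept; the adjusted column is a convenience).
#'
#' @param results named list of ExpressionResult data.frames (any of
#'   `mRNA`, `RPF`, `TE`), each with gene_id and log2fc.
#' @param strata data.frame (gene_id, label) from [assign_strata()]; label
#'   "no_site" marks the background, NA labels are excluded.
#' @param min_genes minimum stratum size for testing (default 10).
#' @param background "no_site" (default) or "all" (all expressed genes).
#' @param seed seed for the bootstrap CIs.
#' @return data.frame (label, level, n, ks_D, ks_p, ks_fdr, median_log2fc,
#'   ci_lo, ci_hi, pearson_r, pearson_p, tested); ECDF coordinates for
#'   plotting are in attribute "ecdf".
#' @export
stratified_analysis <- function(results, strata, min_genes = 10L,
                                background = c("no_site", "all"), seed = 1L) {
  background <- match.arg(background)
  levels_present <- intersect(c("mRNA", "RPF", "TE"), names(results))
  if (!length(levels_present)) stop("no expression-result tables supplied")
  lfc_of <- function(level) {
    r <- results[[level]]
    setNames(r$log2fc, r$gene_id)
  }
  labs <- setdiff(unique(strata$label), c(NA, "no_site"))
  labs <- sort(labs)
  mr <- if ("mRNA" %in% levels_present) lfc_of("mRNA") else NULL
  rp <- if ("RPF" %in% levels_present) lfc_of("RPF") else NULL
  rows <- list()
  ecdfs <- list()
  for (level in levels_present) {
    lfc <- lfc_of(level)
    bg_genes <- if (background == "no_site") {
      strata$gene_id[!is.na(strata$label) & strata$label == "no_site"]
    } else strata$gene_id
    bg <- lfc[intersect(bg_genes, names(lfc))]
    bg <- bg[is.finite(bg)]
    for (lb in labs) {
      genes <- strata$gene_id[!is.na(strata$label) & strata$label == lb]
      v <- lfc[intersect(genes, names(lfc))]
      v <- v[is.finite(v)]
      n <- length(v)
      tested <- n >= min_genes && length(bg) >= min_genes
      ks <- if (tested) ks_shift_test(v, bg) else list(D = NA_real_, p = NA_real_)
      mc <- if (n >= 1) median_with_ci(v, seed = seed)
            else list(median = NA_real_, lo = NA_real_, hi = NA_real_)
      r_p <- c(NA_real_, NA_real_)
      if (!is.null(mr) && !is.null(rp)) {
        gg <- intersect(intersect(genes, names(mr)), names(rp))
        if (length(gg) >= 3) {
          ct <- stats::cor.test(mr[gg], rp[gg])
          r_p <- c(unname(ct$estimate), ct$p.value)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = lb, level = level, n = n, ks_D = ks$D, ks_p = ks$p,
        median_log2fc = mc$median, ci_lo = mc$lo, ci_hi = mc$hi,
        pearson_r = r_p[1], pearson_p = r_p[2], tested = tested,
        stringsAsFactors = FALSE)
      if (tested) {
        sv <- sort(v)
        ecdfs[[paste(level, lb, sep = ":")]] <-
          data.frame(level = level, label = lb, x = sv,
                     ecdf = seq_along(sv) / length(sv))
      }
    }
    if (length(bg)) {
      sb <- sort(bg)
      ecdfs[[paste(level, "no_site", sep = ":")]] <-
        data.frame(level = level, label = "no_site", x = sb,
                   ecdf = seq_along(sb) / length(sb))
    }
  }
  out <- do.call(rbind, rows)
  out$ks_fdr <- NA_real_
  for (level in levels_present) {
    sel <- out$level == level
    out$ks_fdr[sel] <- bh_adjust(out$ks_p[sel])
  }
  out <- out[, c("label", "level", "n", "ks_D", "ks_p", "ks_fdr",
                 "median_log2fc", "ci_lo", "ci_hi", "pearson_r",
                 "pearson_p", "tested")]
  attr(out, "ecdf") <- do.call(rbind, ecdfs)
  out
}

#' Mechanism call from median shifts
#'
#' With m, r, t the median mRNA, RPF and TE log2 shifts of a stratum and
#' delta the effect floor:
#' * `destabilisation_dominant` iff m < -delta and |t| <= |m|/2,
#' * `translation_dominant` iff t < -delta and |m| <= |t|/2,
#' * `mixed` iff m < -delta and t < -delta otherwise,
#' * `none` otherwise.
#'
#' @param m,r,t median log2 shifts at the mRNA, RPF and TE levels.
#' @param delta effect floor (default 0.1).
#' @return list (call, evidence = c(m, r, t)).
#' @export
mechanism_call <- function(m, r, t, delta = 0.1) {
  stopifnot(is.finite(m), is.finite(r), is.finite(t))
  call <- if (m < -delta && abs(t) <= abs(m) / 2) "destabilisation_dominant"
          else if (t < -delta && abs(m) <= abs(t) / 2) "translation_dominant"
          else if (m < -delta && t < -delta) "mixed"
          else "none"
  list(call = call, evidence = c(mRNA = m, RPF = r, TE = t))
}

#' Correlation of fold changes across two conditions
#'
#' @param resultsA,resultsB ExpressionResult data.frames at one level for
#'   two experiments (e.g. overexpression and knockdown).
#' @param selection gene selection: "significant_both" (significant in both
#'   results), "all" (shared universe), or a character vector of gene ids.
#' @return list (r, p, n).
#' @export
cross_condition_correlation <- function(resultsA, resultsB,
                                        selection = "significant_both") {
  shared <- intersect(resultsA$gene_id, resultsB$gene_id)
  a <- resultsA[match(shared, resultsA$gene_id), ]
  b <- resultsB[match(shared, resultsB$gene_id), ]
  genes <- if (identical(selection, "significant_both")) {
    shared[a$significant & b$significant]
  } else if (identical(selection, "all")) {
    shared
  } else {
    intersect(shared, selection)
  }
  if (length(genes) < 3) stop("fewer than 3 genes selected for correlation")
  i <- match(genes, shared)
  ct <- stats::cor.test(a$log2fc[i], b$log2fc[i])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(genes))
}

#' One-sided hypergeometric over-representation test
#'
#' Generic plumbing for gene-set over-representation on user-supplied sets
#' (makes no claim to reproduce any specific enrichment web service).
#'
#' @param genes character vector of selected genes.
#' @param universe character vector of background genes.
#' @param sets named list of gene sets.
#' @return data.frame (set, overlap, set_size, pvalue, fdr).
#' @export
overrepresentation_test <- function(genes, universe, sets) {
  genes <- intersect(genes, universe)
  n_u <- length(universe)
  n_g <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, genes))
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_g,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s), pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out
}
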