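# Canonical miRNA seed-site prediction and context scoring.
#
# Site definitions (target strand, 5'->3'):
#   6mer     : reverse complement of miRNA nt 2-7
#   7mer-1a  : 6mer followed by an A opposite miRNA position 1
#   7mer-m8  : reverse complement of miRNA nt 2-8
#   8mer     : 7mer-m8 followed by an A
# Every canonical site contains the 6mer core; a locus (one core occurrence)
# is reported once as its strongest type: 8mer > 7mer-m8 > 7mer-1a > 6mer.
# Coordinates are 0-based offsets of the first matched nucleotide within the
# region sequence.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-1a", "6mer")
SITE_LEN <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-1a" = 7L, "6mer" = 6L)

#' Seed-match patterns for a mature miRNA
#'
#' @param mirna mature miRNA sequence, 5'->3' (T accepted, mapped to U).
#' @return named list with the target-strand match strings `core` (6mer),
#'   `m8` (single base pairing miRNA position 8) and the four full site
#'   patterns.
#' @export
seed_patterns <- function(mirna) {
  mirna <- as_rna(mirna, "miRNA")
  if (nchar(mirna) < 8L) stop("miRNA sequence must be at least 8 nt")
  core <- rna_revcomp(substr(mirna, 2L, 7L))  # pairs miRNA nt 2-7
  m8 <- rna_comp1(substr(mirna, 8L, 8L))      # pairs miRNA nt 8
  list(core = core, m8 = m8,
       `8mer` = paste0(m8, core, "A"),
       `7mer-m8` = paste0(m8, core),
       `7mer-1a` = paste0(core, "A"),
       `6mer` = core)
}

#' Find canonical seed-match sites in a region sequence
#'
#' Scans every position of `region_sequence` for canonical seed matches to
#' `mirna_sequence` and resolves overlapping classifications at one locus to
#' the single strongest type (8mer > 7mer-m8 > 7mer-1a > 6mer).
#'
#' @param region_sequence target region sequence(s), 5'->3' (character
#'   vector; T accepted).
#' @param mirna_sequence mature miRNA sequence, 5'->3'.
#' @param min_type weakest site type to report (default "6mer" reports all).
#' @return data.frame with columns `start` (0-based offset of the first
#'   matched nucleotide), `site_type`, and `seq_index` (which element of
#'   `region_sequence` the site belongs to), ordered by `seq_index` then
#'   `start`.
#' @export
find_seed_sites <- function(region_sequence, mirna_sequence,
                            min_type = "6mer") {
  seqs <- as_rna(region_sequence, "region sequence")
  pat <- seed_patterns(mirna_sequence)
  min_rank <- match(match.arg(min_type, SITE_TYPES), SITE_TYPES)

  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    # all core occurrences, including self-overlapping ones (1-based starts)
    q <- core_starts(s, pat$core)
    if (!length(q)) next
    prev <- ifelse(q > 1L, substr(rep(s, length(q)), q - 1L, q - 1L), "")
    nxt <- ifelse(q + 6L <= n, substr(rep(s, length(q)), q + 6L, q + 6L), "")
    is_m8 <- prev == pat$m8
    is_a <- nxt == "A"
    type <- ifelse(is_m8 & is_a, "8mer",
            ifelse(is_m8, "7mer-m8",
            ifelse(is_a, "7mer-1a", "6mer")))
    start0 <- ifelse(is_m8, q - 2L, q - 1L)  # to 0-based site start
    keep <- match(type, SITE_TYPES) <= min_rank
    if (!any(keep)) next
    out[[i]] <- data.frame(seq_index = i, start = as.integer(start0[keep]),
                           site_type = type[keep], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(seq_index = integer(), start = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_index, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# all (possibly overlapping) 1-based start positions of `pattern` in `s`
core_starts <- function(s, pattern) {
  k <- nchar(pattern)
  n <- nchar(s)
  if (n < k) return(integer())
  starts <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(pattern, substr(s, from, n), fixed = TRUE)
    if (hit == -1L) break
    pos <- from + as.integer(hit) - 1L
    starts <- c(starts, pos)
    from <- pos + 1L
  }
  starts
}

#' Default context-score coefficients
#'
#' A documented three-feature surrogate for the trained TargetScan context++
#' model: a site-type base score, a local AU-content term, and a positional
#' term. More negative scores predict stronger repression.
#'
#' @param base_8mer,base_7mer_m8,base_7mer_1a,base_6mer per-type base scores.
#' @param w_au weight on (local AU fraction in +/-30 nt flanks - 0.5).
#' @param w_pos weight on min(distance to nearest region boundary, 1500)/1500.
#' @return named list of coefficients.
#' @export
score_coefficients <- function(base_8mer = -0.31, base_7mer_m8 = -0.16,
                               base_7mer_1a = -0.10, base_6mer = -0.02,
                               w_au = -0.1, w_pos = 0.05) {
  list(base = c("8mer" = base_8mer, "7mer-m8" = base_7mer_m8,
                "7mer-1a" = base_7mer_1a, "6mer" = base_6mer),
       w_au = w_au, w_pos = w_pos)
}

#' Context score for predicted seed sites
#'
#' `score = base(site_type) + w_au * (AU fraction in the +/-30 nt flanks - 0.5)
#'        + w_pos * min(distance to the nearest region boundary, 1500)/1500`
#'
#' With the default coefficients 8mer sites score strictly more negative than
#' 7mer-m8, then 7mer-1a, then 6mer at equal context; AU-rich flanks and
#' boundary-proximal positions are more repressive.
#'
#' @param sites data.frame from [find_seed_sites()] (columns `start`,
#'   `site_type`, and optionally `seq_index`).
#' @param region_sequence the region sequence(s) the sites were found in.
#' @param coeffs coefficients from [score_coefficients()].
#' @param flank flank width in nt for the AU term (default 30).
#' @return `sites` with a `context_score` column appended.
#' @export
score_sites <- function(sites, region_sequence,
                        coeffs = score_coefficients(), flank = 30L) {
  seqs <- as_rna(region_sequence, "region sequence")
  if (!nrow(sites)) {
    sites$context_score <- numeric(0)
    return(sites)
  }
  idx <- if ("seq_index" %in% names(sites)) sites$seq_index else rep(1L, nrow(sites))
  len <- SITE_LEN[sites$site_type]
  n <- nchar(seqs)[idx]
  s1 <- sites$start + 1L                       # 1-based site start
  lo <- pmax(1L, s1 - flank)
  hi <- pmin(n, s1 + len - 1L + flank)
  left <- substr(seqs[idx], lo, s1 - 1L)
  right <- substr(seqs[idx], s1 + len, hi)
  fl <- paste0(left, right)
  au <- ifelse(nchar(fl) > 0L,
               (nchar(fl) - nchar(gsub("[AU]", "", fl))) / nchar(fl), 0.5)
  dist <- pmin(sites$start, n - (sites$start + len))
  pos <- pmin(dist, 1500L) / 1500
  sites$context_score <- unname(coeffs$base[sites$site_type] +
                                coeffs$w_au * (au - 0.5) + coeffs$w_pos * pos)
  sites
}

#' Scan and score a set of genes for one miRNA
#'
#' Convenience wrapper: runs [find_seed_sites()] and [score_sites()] over
#' named 3'UTR and CDS sequences and returns one site table.
#'
#' @param utr3,cds named character vectors of region sequences (names are
#'   gene ids); either may be NULL.
#' @param mirna mature miRNA sequence.
#' @param coeffs score coefficients.
#' @param min_type weakest site type to report.
#' @return data.frame (gene_id, region, start, site_type, context_score);
#'   `region` is "utr3" or "cds"; `start` is 0-based within the region.
#' @export
scan_genes <- function(utr3 = NULL, cds = NULL, mirna,
                       coeffs = score_coefficients(), min_type = "6mer") {
  one_region <- function(seqs, region) {
    if (is.null(seqs) || !length(seqs)) return(NULL)
    st <- find_seed_sites(seqs, mirna, min_type = min_type)
    st <- score_sites(st, seqs, coeffs = coeffs)
    if (!nrow(st)) return(NULL)
    data.frame(gene_id = names(seqs)[st$seq_index], region = region,
               start = st$start, site_type = st$site_type,
               context_score = st$context_score, stringsAsFactors = FALSE)
  }
  out <- rbind(one_region(utr3, "utr3"), one_region(cds, "cds"))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), region = character(),
                      start = integer(), site_type = character(),
                      context_score = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate site scores per gene and apply the context-score filter
#'
#' Sums 3'UTR site context scores into CWCS (cumulative weighted context++
#' score analog) and CDS site scores into TCS (total context+ score analog).
#' A gene is a filtered 3'UTR target when CWCS < `threshold` *and* it has no
#' CDS site; a filtered CDS target when TCS < `threshold` *and* it has no
#' 3'UTR site (for region-specific analyses genes with sites in the other
#' region are excluded). Genes with no sites are absent from the annotation.
#'
#' @param sites site table from [scan_genes()] (gene_id, region, start,
#'   site_type, context_score).
#' @param threshold context-score filter (default -0.2): retained when the
#'   aggregate score is strictly below it.
#' @param pct optional named numeric vector of probability-of-conserved-
#'   targeting values per gene (missing genes get NA).
#' @return data.frame with one row per gene having >= 1 site: gene_id,
#'   n_sites, n_utr3, n_cds, cwcs, tcs, region_class
#'   ("utr3_only"/"cds_only"/"both"), utr3_target, cds_target, pct.
#' @export
aggregate_targets <- function(sites, threshold = -0.2, pct = NULL) {
  if (!nrow(sites)) {
    return(data.frame(gene_id = character(), n_sites = integer(),
                      n_utr3 = integer(), n_cds = integer(), cwcs = numeric(),
                      tcs = numeric(), region_class = character(),
                      utr3_target = logical(), cds_target = logical(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  genes <- sort(unique(sites$gene_id))
  f <- factor(sites$gene_id, levels = genes)
  is_u <- sites$region == "utr3"
  n_utr3 <- as.integer(tapply(is_u, f, sum, default = 0))
  n_cds <- as.integer(tapply(!is_u, f, sum, default = 0))
  sum_by <- function(x, keep) {
    v <- ifelse(keep, x, 0)
    as.numeric(tapply(v, f, sum, default = 0))
  }
  cwcs <- sum_by(sites$context_score, is_u)
  tcs <- sum_by(sites$context_score, !is_u)
  region_class <- ifelse(n_utr3 > 0L & n_cds > 0L, "both",
                  ifelse(n_utr3 > 0L, "utr3_only", "cds_only"))
  ann <- data.frame(gene_id = genes, n_sites = n_utr3 + n_cds,
                    n_utr3 = n_utr3, n_cds = n_cds, cwcs = cwcs, tcs = tcs,
                    region_class = region_class,
                    utr3_target = n_cds == 0L & cwcs < threshold,
                    cds_target = n_utr3 == 0L & tcs < threshold,
                    stringsAsFactors = FALSE)
  ann$pct <- if (is.null(pct)) NA_real_ else unname(pct[ann$gene_id])
  ann
}

#' Assign stratification labels to expressed genes
#'
#' @param annotations target annotation table from [aggregate_targets()].
#' @param universe character vector of expressed gene ids; genes not in the
#'   annotation (or excluded by the scheme's filter) get label "no_site".
#' @param scheme one of:
#'   * `pct_group`: "high" (Pct > 0.5), "low" (0 < Pct <= 0.5),
#'     "nonconserved" (Pct = 0) among filtered 3'UTR targets;
#'   * `cwcs_quartile`: empirical quartiles of CWCS among filtered 3'UTR
#'     targets, Q1 the most negative; boundary values go to the lower (more
#'     repressive) quartile;
#'   * `seed_type`: "multi_site" (> 1 site in `region`), else the single
#'     site's type; genes whose only site is a 6mer are excluded (NA);
#'   * `region_class`: "utr3_only", "cds_only", "both".
#' @param sites site table (required for the `seed_type` scheme).
#' @param region region the seed_type scheme counts sites in ("utr3"/"cds").
#' @param filtered for pct_group/cwcs_quartile/seed_type, restrict target
#'   labels to filtered targets of `region` (default TRUE, matching the
#'   context-score filtration used for those analyses).
#' @return data.frame (gene_id, label); label NA marks genes excluded from
#'   the scheme (neither target stratum nor background).
#' @export
assign_strata <- function(annotations, universe,
                          scheme = c("pct_group", "cwcs_quartile",
                                     "seed_type", "region_class"),
                          sites = NULL, region = "utr3", filtered = TRUE) {
  scheme <- match.arg(scheme)
  lab <- setNames(rep("no_site", length(universe)), universe)
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  tgt_flag <- if (region == "utr3") ann$utr3_target else ann$cds_target
  has_any <- ann$gene_id   # genes with any site: never background
  lab[has_any] <- NA_character_

  if (scheme == "region_class") {
    lab[ann$gene_id] <- ann$region_class
  } else if (scheme == "pct_group") {
    tg <- ann[if (filtered) tgt_flag else ann$n_utr3 > 0L, , drop = FALSE]
    if (nrow(tg)) {
      if (all(is.na(tg$pct))) stop("pct_group scheme requires Pct values")
      lab[tg$gene_id] <- ifelse(tg$pct > 0.5, "high",
                         ifelse(tg$pct > 0, "low", "nonconserved"))
    }
  } else if (scheme == "cwcs_quartile") {
    score <- if (region == "utr3") ann$cwcs else ann$tcs
    tg_idx <- if (filtered) tgt_flag else (if (region == "utr3") ann$n_utr3 else ann$n_cds) > 0L
    sc <- score[tg_idx]
    g <- ann$gene_id[tg_idx]
    if (length(sc)) {
      qs <- stats::quantile(sc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      # boundary values to the lower (more negative, more repressive) quartile
      ql <- ifelse(sc <= qs[1], "Q1", ifelse(sc <= qs[2], "Q2",
            ifelse(sc <= qs[3], "Q3", "Q4")))
      lab[g] <- ql
    }
  } else { # seed_type
    if (is.null(sites)) stop("seed_type scheme requires the site table")
    tg <- ann[if (filtered) tgt_flag else rep(TRUE, nrow(ann)), , drop = FALSE]
    rs <- sites[sites$region == region & sites$gene_id %in% tg$gene_id, , drop = FALSE]
    if (nrow(rs)) {
      cnt <- table(rs$gene_id)
      multi <- names(cnt)[cnt > 1L]
      single <- rs[rs$gene_id %in% names(cnt)[cnt == 1L], , drop = FALSE]
      lab[multi] <- "multi_site"
      keep <- single$site_type != "6mer"   # 6mer-only genes excluded
      lab[single$gene_id[keep]] <- single$site_type[keep]
    }
  }
  data.frame(gene_id = universe, label = unname(lab[universe]),
             stringsAsFactors = FALSE)
}

#' Read a TargetScan "Predicted Targets" style table
#'
#' Accepts the tab-separated predicted-targets layout with gene symbol, site
#' type, context++ score and Pct columns (column names matched loosely), and
#' converts it to the package's site-table layout so externally predicted
#' sites can bypass the built-in surrogate scorer.
#'
#' @param path TSV file path.
#' @return list with `sites` (gene_id, region, start, site_type,
#'   context_score) and `pct` (named numeric vector).
#' @export
read_targetscan <- function(path) {
  x <- read_tsv(path)
  nm <- tolower(names(x))
  pick <- function(patterns) {
    for (p in patterns) {
      i <- grep(p, nm)
      if (length(i)) return(i[1L])
    }
    NA_integer_
  }
  gi <- pick(c("^gene.?symbol$", "^gene.?id$", "^target"))
  ti <- pick(c("site.?type", "seed.?match"))
  ci <- pick(c("context", "cwcs"))
  pi <- pick(c("pct", "p_ct", "conserv"))
  si <- pick(c("utr.?start", "^start$", "position"))
  if (is.na(gi) || is.na(ti)) stop("cannot locate gene / site-type columns")
  type_raw <- tolower(gsub("[ _]", "", x[[ti]]))
  type <- ifelse(grepl("8mer", type_raw), "8mer",
          ifelse(grepl("m8", type_raw), "7mer-m8",
          ifelse(grepl("1a|a1", type_raw), "7mer-1a", "6mer")))
  sites <- data.frame(
    gene_id = as.character(x[[gi]]), region = "utr3",
    start = if (is.na(si)) NA_integer_ else as.integer(x[[si]]),
    site_type = type,
    context_score = if (is.na(ci)) NA_real_ else as.numeric(x[[ci]]),
    stringsAsFactors = FALSE)
  pct <- NULL
  if (!is.na(pi)) {
    p <- suppressWarnings(as.numeric(x[[pi]]))
    p[is.na(p)] <- 0
    pct <- tapply(p, sites$gene_id, max)
    pct <- setNames(as.numeric(pct), names(pct))
  }
  list(sites = sites, pct = pct)
}
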