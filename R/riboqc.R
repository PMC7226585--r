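# Ribosome-profiling QC: feature-alignment proportions, P-site offset
# calibration, sub-codon phasing, metagene profiles. Alignments are
# transcript-coordinate BED-like records (transcript_id, start, end, length)
# with 0-based half-open coordinates; regions partition each transcript as
# 5'UTR | CDS | 3'UTR.
#
# Conventions: Ribo-Seq reads are assigned by P site (5' end + offset);
# mRNA-Seq reads by fragment midpoint. Frames are 0-indexed, frame 0 being
# the canonical frame (elsewhere often counted as "frame 1").

check_regions <- function(regions) {
  stopifnot(all(c("transcript_id", "utr5_len", "cds_len", "utr3_len")
                %in% names(regions)))
  regions
}

# per-read assigned position: P site for rpf, midpoint for mrna
read_positions <- function(alignments, psite_offsets = NULL,
                           assay = c("rpf", "mrna")) {
  assay <- match.arg(assay)
  if (assay == "mrna") return((alignments$start + alignments$end) %/% 2L)
  if (is.null(psite_offsets)) stop("rpf position assignment needs P-site offsets")
  if (is.data.frame(psite_offsets)) {
    off <- setNames(psite_offsets$offset, psite_offsets$length)
  } else if (!is.null(names(psite_offsets))) {
    off <- psite_offsets
  } else {
    return(alignments$start + as.integer(psite_offsets[1L]))
  }
  o <- off[as.character(alignments$length)]
  if (anyNA(o)) stop("P-site offset missing for some read lengths")
  alignments$start + as.integer(o)
}

#' Proportion of reads aligning to each transcript feature
#'
#' Each read is assigned to the region (5'UTR, CDS, 3'UTR) containing its
#' P site (Ribo-Seq) or fragment midpoint (mRNA-Seq). Reads whose assigned
#' position falls outside the transcript are counted as discarded.
#'
#' @param alignments data.frame (transcript_id, start, end, length).
#' @param regions region table (transcript_id, utr5_len, cds_len, utr3_len).
#' @param assay "rpf" (P-site rule) or "mrna" (midpoint rule).
#' @param psite_offsets offset(s) for the P-site rule: scalar, named vector
#'   by read length, or the data.frame from [estimate_psite_offsets()].
#' @return list with `proportions` (named, sums to 1 over utr5/cds/utr3),
#'   `counts`, and `discarded`.
#' @export
region_alignment_stats <- function(alignments, regions, assay = "rpf",
                                   psite_offsets = 12) {
  regions <- check_regions(regions)
  i <- match(alignments$transcript_id, regions$transcript_id)
  if (anyNA(i)) stop("alignments reference unknown transcripts")
  pos <- read_positions(alignments, psite_offsets, assay)
  u5 <- regions$utr5_len[i]
  cds <- regions$cds_len[i]
  total <- u5 + cds + regions$utr3_len[i]
  ok <- pos >= 0L & pos < total
  reg <- ifelse(pos < u5, "utr5", ifelse(pos < u5 + cds, "cds", "utr3"))
  cnt <- c(utr5 = sum(ok & reg == "utr5"), cds = sum(ok & reg == "cds"),
           utr3 = sum(ok & reg == "utr3"))
  list(proportions = cnt / sum(cnt), counts = cnt, discarded = sum(!ok))
}

#' Estimate P-site offsets per read length
#'
#' For each read length, the offset is the modal distance from the read 5'
#' end to the annotated start codon among reads overlapping a start codon
#' (the cross-correlation peak between 5'-end positions and start codons).
#' Length classes with fewer than `min_reads` start-overlapping reads fall
#' back to the global modal offset and are flagged.
#'
#' @param alignments footprint alignments (transcript_id, start, end, length).
#' @param regions region table.
#' @param min_reads minimum start-overlapping reads per length class.
#' @return data.frame (length, offset, n, fallback).
#' @export
estimate_psite_offsets <- function(alignments, regions, min_reads = 500L) {
  regions <- check_regions(regions)
  i <- match(alignments$transcript_id, regions$transcript_id)
  if (anyNA(i)) stop("alignments reference unknown transcripts")
  d <- regions$utr5_len[i] - alignments$start   # 5' end -> start codon
  ov <- d >= 0L & d < alignments$length         # read overlaps the start
  if (!any(ov)) stop("no reads overlap annotated start codons")
  d <- d[ov]
  len <- alignments$length[ov]
  modal <- function(v) as.integer(names(which.max(table(v))))
  global_mode <- modal(d)
  lens <- sort(unique(alignments$length))
  out <- do.call(rbind, lapply(lens, function(l) {
    dl <- d[len == l]
    fb <- length(dl) < min_reads
    data.frame(length = l,
               offset = if (fb) global_mode else modal(dl),
               n = length(dl), fallback = fb)
  }))
  rownames(out) <- NULL
  out
}

#' Sub-codon phasing of footprint P sites
#'
#' Frame = (P-site position - CDS start) mod 3 over reads whose P site lies
#' in the CDS interior (first and last codons excluded, to keep initiation
#' and termination pile-ups from inflating one frame).
#'
#' @param alignments footprint alignments.
#' @param psite_offsets as in [region_alignment_stats()].
#' @param regions region table.
#' @return list with `frame_fractions` (length-3, sums to 1; frame 0 is
#'   canonical), `dominant_frame` (0-indexed), `n_reads`.
#' @export
phasing_fractions <- function(alignments, psite_offsets, regions) {
  regions <- check_regions(regions)
  i <- match(alignments$transcript_id, regions$transcript_id)
  pos <- read_positions(alignments, psite_offsets, "rpf")
  u5 <- regions$utr5_len[i]
  cds_end <- u5 + regions$cds_len[i]
  inside <- pos >= u5 + 3L & pos < cds_end - 3L
  if (!any(inside)) stop("no P sites in the CDS interior")
  fr <- (pos[inside] - u5[inside]) %% 3L
  tab <- tabulate(fr + 1L, nbins = 3L)
  frac <- tab / sum(tab)
  list(frame_fractions = setNames(frac, paste0("frame", 0:2)),
       dominant_frame = which.max(frac) - 1L, n_reads = sum(inside))
}

#' Metagene profile around start or stop codons
#'
#' Read density per offset relative to the first nucleotide of the start (or
#' stop) codon, summed over transcripts after scaling each transcript's
#' windowed profile to unit mean. Transcripts that cannot contain the full
#' window (or have no reads in it) are excluded and counted.
#'
#' @param alignments alignments table.
#' @param regions region table.
#' @param window integer c(lo, hi) window of offsets (default -50..100).
#' @param anchor "start" or "stop" codon.
#' @param assay,psite_offsets position-assignment rule, as elsewhere.
#' @return list with `offsets`, `density`, `n_transcripts`, `n_excluded`.
#' @export
metagene_profile <- function(alignments, regions, window = c(-50L, 100L),
                             anchor = c("start", "stop"), assay = "rpf",
                             psite_offsets = 12) {
  anchor <- match.arg(anchor)
  regions <- check_regions(regions)
  total <- regions$utr5_len + regions$cds_len + regions$utr3_len
  anchor_pos <- if (anchor == "start") regions$utr5_len
                else regions$utr5_len + regions$cds_len - 3L
  eligible <- anchor_pos + window[1] >= 0L & anchor_pos + window[2] < total
  width <- window[2] - window[1] + 1L
  offs <- window[1]:window[2]
  pos <- read_positions(alignments, psite_offsets, assay)
  i <- match(alignments$transcript_id, regions$transcript_id)
  rel <- pos - anchor_pos[i]
  use <- eligible[i] & rel >= window[1] & rel <= window[2]
  if (!any(use)) stop("no eligible transcripts with reads in the window")
  f <- factor(alignments$transcript_id[use],
              levels = unique(alignments$transcript_id[use]))
  dens <- numeric(width)
  for (r in split(rel[use] - window[1] + 1L, f)) {
    cnt <- tabulate(r, nbins = width)
    dens <- dens + cnt / mean(cnt)
  }
  list(offsets = offs, density = dens, n_transcripts = nlevels(f),
       n_excluded = sum(!eligible))
}

#' Full QC report
#'
#' Convenience wrapper running offset estimation, phasing, region stats and
#' start/stop metagene profiles on one footprint alignment set.
#'
#' @param alignments footprint alignments.
#' @param regions region table.
#' @param window metagene window.
#' @param min_reads minimum reads per length class for offset estimation.
#' @return list (psite_offsets, phasing, region_stats, metagene_start,
#'   metagene_stop).
#' @export
ribo_qc_report <- function(alignments, regions, window = c(-50L, 100L),
                           min_reads = 500L) {
  off <- estimate_psite_offsets(alignments, regions, min_reads = min_reads)
  list(psite_offsets = off,
       phasing = phasing_fractions(alignments, off, regions),
       region_stats = region_alignment_stats(alignments, regions, "rpf", off),
       metagene_start = metagene_profile(alignments, regions, window,
                                         "start", "rpf", off),
       metagene_stop = metagene_profile(alignments, regions, window,
                                        "stop", "rpf", off))
}
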