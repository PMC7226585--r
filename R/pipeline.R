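# Pipeline orchestration: simulate -> scan -> qc -> de -> stratify -> panel,
# driven by a plain-text (TOML-subset) config, with per-stage manifests and
# a consolidated JSON report. Per-stage RNG seeds are derived from the
# master seed by fixed offsets so any stage is reproducible in isolation.

default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = ".",
    thresholds = list(fdr = 0.05, lfc = 0.5, context = -0.2, pct_cut = 0.5),
    steps = list(simulate = TRUE, scan = TRUE, qc = TRUE, de = TRUE,
                 stratify = TRUE, panel = TRUE),
    simulate = list(n_genes = 300, target_fraction = 0.3,
                    lib_size_mean = 3e5, dispersion = 0.1, n_reads = 5e4),
    panel = list(mirnas = c("miR-96-5p-like", "miR-182-5p-like",
                            "miR-183-5p-like", "let-7b-5p-like"),
                 true_log2fc = c(2.78, 0.6, 0.6, 0),
                 n_replicates = 4, noise_sd = 0.3)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

stage_seed <- function(master, stage) {
  offsets <- c(simulate = 1L, scan = 2L, qc = 3L, de = 4L, stratify = 5L,
               panel = 6L)
  as.integer((as.integer(master) %% 20000000L) * 100L + offsets[[stage]])
}

write_manifest <- function(outdir, stage, params, inputs = character()) {
  checks <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(stage = stage, parameters = params,
                   input_checksums = checks)
  jsonlite::write_json(manifest, file.path(outdir,
                                           paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on simulated data,
#' writing TSV/JSON outputs, a manifest per stage, and a consolidated
#' report. Fully deterministic under a fixed config: re-running with the
#' same config produces byte-identical result files.
#'
#' @param config a nested list (see `read_config()` for the file form);
#'   missing entries fall back to packaged defaults. Keys: `seed`, `outdir`,
#'   `thresholds` (fdr, lfc, context, pct_cut), `steps` (logical toggles),
#'   `simulate` (n_genes, target_fraction, lib_size_mean, dispersion,
#'   n_reads, plus any [sim_config()] argument), `panel`.
#' @param outdir output directory (overrides `config$outdir`).
#' @return invisible list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  report <- list(seed = cfg$seed, stages = list())
  run_stage <- function(stage, fn) {
    if (!isTRUE(cfg$steps[[stage]])) return(NULL)
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sim <- run_stage("simulate", function() {
    sc_args <- cfg$simulate
    sc_args$n_reads <- NULL
    sc_args$seed <- stage_seed(cfg$seed, "simulate")
    sc <- do.call(sim_config, sc_args)
    txm <- generate_transcriptome(sc)
    cm <- simulate_counts(txm$truth, sc)
    fp <- simulate_footprints(txm$transcripts, sc,
                              n_reads = cfg$simulate$n_reads)
    tx <- txm$transcripts
    write_fasta(setNames(tx$utr3, tx$transcript_id),
                file.path(cfg$outdir, "utr3.fa"))
    write_fasta(setNames(tx$cds, tx$transcript_id),
                file.path(cfg$outdir, "cds.fa"))
    write_tsv(region_table(tx), file.path(cfg$outdir, "regions.tsv"))
    write_tsv(data.frame(gene_id = rownames(cm$counts), cm$counts,
                         check.names = FALSE),
              file.path(cfg$outdir, "counts.tsv"))
    write_tsv(cm$design, file.path(cfg$outdir, "design.tsv"))
    write_tsv(fp, file.path(cfg$outdir, "footprints.tsv"))
    write_tsv(txm$truth$genes, file.path(cfg$outdir, "truth_genes.tsv"))
    write_tsv(txm$truth$sites, file.path(cfg$outdir, "truth_sites.tsv"))
    write_manifest(cfg$outdir, "simulate",
                   list(seed = sc_args$seed, n_genes = sc$n_genes))
    list(sim_config = sc, transcriptome = txm, counts = cm, footprints = fp)
  })
  out$simulate <- sim
  if (is.null(sim)) return(invisible(out))

  scan <- run_stage("scan", function() {
    tx <- sim$transcriptome$transcripts
    sites <- scan_genes(utr3 = setNames(tx$utr3, tx$transcript_id),
                        cds = setNames(tx$cds, tx$transcript_id),
                        mirna = sim$sim_config$mirna)
    pct <- setNames(sim$transcriptome$truth$genes$pct,
                    sim$transcriptome$truth$genes$gene_id)
    ann <- aggregate_targets(sites, threshold = cfg$thresholds$context,
                             pct = pct)
    write_tsv(sites, file.path(cfg$outdir, "sites.tsv"))
    write_tsv(ann, file.path(cfg$outdir, "target_annotations.tsv"))
    write_manifest(cfg$outdir, "scan",
                   list(threshold = cfg$thresholds$context),
                   file.path(cfg$outdir, c("utr3.fa", "cds.fa")))
    list(sites = sites, annotations = ann)
  })
  out$scan <- scan

  qc <- run_stage("qc", function() {
    regions <- region_table(sim$transcriptome$transcripts)
    rep_qc <- ribo_qc_report(sim$footprints, regions, min_reads = 200L)
    write_tsv(rep_qc$psite_offsets, file.path(cfg$outdir, "psite_offsets.tsv"))
    qc_json <- list(
      frame_fractions = as.list(rep_qc$phasing$frame_fractions),
      dominant_frame = rep_qc$phasing$dominant_frame,
      region_proportions = as.list(rep_qc$region_stats$proportions),
      discarded_reads = rep_qc$region_stats$discarded)
    jsonlite::write_json(qc_json, file.path(cfg$outdir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv(data.frame(offset = rep_qc$metagene_start$offsets,
                         density = rep_qc$metagene_start$density),
              file.path(cfg$outdir, "metagene_start.tsv"))
    write_manifest(cfg$outdir, "qc", list(min_reads = 200),
                   file.path(cfg$outdir, "footprints.tsv"))
    report$stages$qc <<- qc_json
    rep_qc
  })
  out$qc <- qc

  de <- run_stage("de", function() {
    cm <- sim$counts
    des <- cm$design
    split_assay <- function(a) {
      sel <- des$assay == a
      list(counts = cm$counts[, sel, drop = FALSE],
           design = des[sel, , drop = FALSE])
    }
    mr <- split_assay("mrna")
    rp <- split_assay("rpf")
    res <- list(
      mRNA = de_analysis(mr$counts, mr$design, "mRNA",
                         fdr = cfg$thresholds$fdr, lfc = cfg$thresholds$lfc),
      RPF = de_analysis(rp$counts, rp$design, "RPF",
                        fdr = cfg$thresholds$fdr, lfc = cfg$thresholds$lfc))
    shared <- intersect(res$mRNA$gene_id, res$RPF$gene_id)
    res$TE <- test_differential_te(
      mr$counts[shared, , drop = FALSE], rp$counts[shared, , drop = FALSE],
      mr$design, rp$design,
      fdr = cfg$thresholds$fdr, lfc = cfg$thresholds$lfc)
    all_res <- do.call(rbind, lapply(res, function(x)
      x[, c("gene_id", "level", "log2fc", "pvalue", "fdr", "significant")]))
    write_tsv(all_res, file.path(cfg$outdir, "de_results.tsv"))
    write_manifest(cfg$outdir, "de", cfg$thresholds,
                   file.path(cfg$outdir, c("counts.tsv", "design.tsv")))
    report$stages$de <<- lapply(res, function(x)
      list(n_genes = nrow(x), n_significant = sum(x$significant, na.rm = TRUE)))
    res
  })
  out$de <- de

  strat <- run_stage("stratify", function() {
    universe <- de$mRNA$gene_id
    comps <- list()
    for (scheme in c("pct_group", "cwcs_quartile", "seed_type",
                     "region_class")) {
      st <- assign_strata(scan$annotations, universe, scheme,
                          sites = scan$sites)
      comp <- stratified_analysis(de, st,
                                  seed = stage_seed(cfg$seed, "stratify"))
      comp$scheme <- scheme
      comps[[scheme]] <- comp
    }
    all_comp <- do.call(rbind, comps)
    all_comp <- all_comp[, c("scheme", setdiff(names(all_comp), "scheme"))]
    write_tsv(all_comp, file.path(cfg$outdir, "strata_comparisons.tsv"))
    # mechanism call on the filtered 3'UTR target stratum (region scheme)
    med_of <- function(level) {
      x <- comps$region_class
      v <- x$median_log2fc[x$level == level & x$label == "utr3_only"]
      if (length(v)) v else NA_real_
    }
    mech <- if (all(is.finite(c(med_of("mRNA"), med_of("RPF"),
                                med_of("TE"))))) {
      mechanism_call(med_of("mRNA"), med_of("RPF"), med_of("TE"))
    } else list(call = "none", evidence = NULL)
    jsonlite::write_json(mech, file.path(cfg$outdir, "mechanism.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(cfg$outdir, "stratify",
                   list(seed = stage_seed(cfg$seed, "stratify")),
                   file.path(cfg$outdir, c("de_results.tsv", "sites.tsv")))
    report$stages$stratify <<- list(mechanism = mech$call,
                                    n_comparisons = nrow(all_comp))
    list(comparisons = all_comp, mechanism = mech)
  })
  out$stratify <- strat

  panel <- run_stage("panel", function() {
    pc <- cfg$panel
    ct <- simulate_ct_table(pc$mirnas, pc$true_log2fc,
                            n_replicates = pc$n_replicates,
                            noise_sd = pc$noise_sd,
                            seed = stage_seed(cfg$seed, "panel"))
    write_tsv(ct, file.path(cfg$outdir, "ct_table.tsv"))
    res <- panel_analysis(ct, q = cfg$thresholds$fdr)
    write_tsv(res, file.path(cfg$outdir, "panel_results.tsv"))
    write_manifest(cfg$outdir, "panel",
                   list(seed = stage_seed(cfg$seed, "panel"),
                        q = cfg$thresholds$fdr))
    report$stages$panel <<- list(
      n_significant = sum(res$bky_significant))
    res
  })
  out$panel <- panel

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Run the pipeline from a config file
#' @param path TOML-subset config file (see [read_config()]).
#' @param outdir optional output directory override.
#' @export
run_pipeline_file <- function(path, outdir = NULL) {
  run_pipeline(read_config(path), outdir = outdir)
}
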