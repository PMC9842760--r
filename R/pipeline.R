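#' End-to-end pipeline on synthetic or user data
#'
#' Orchestrates simulate -> differential expression (C1-C4) -> ISG
#' classification -> promoter motif scan -> peak annotation/differential
#' calling -> motif enrichment -> report. Configuration is a YAML file (or
#' an equivalent named list) with per-stage sections; every threshold is a
#' named key with the pipeline defaults. All outputs are plain TSV/FASTA/
#' BED/JSON; a manifest lists each output with its MD5 content hash.
#'
#' @param config Path to a YAML config file, or a named list. Recognized
#'   sections: `simulate` (arguments of [sim_config()]), `thresholds`
#'   (`lfc_min`, `padj_max` or `p_max`), `reference`
#'   (`reported_fraction`), `motifs` (`threshold`), `peaks`
#'   (`proximal_cutoff`, `fc_min`, `padj_max`, `direction`). Missing
#'   sections use defaults.
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return Invisibly, a list with the fit, classification report,
#'   enrichment table and the manifest path. Writes
#'   `report.json`, `manifest.json` and per-stage TSVs under `outdir`.
#' @export
run_isg_pipeline <- function(config = NULL, outdir, seed = NULL) {
  cfg_list <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg_list <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    cfg_list <- config
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  sim_args <- cfg_list$simulate
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  scfg <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)

  sim <- stage("simulate", {
    sim <- simulate_counts(scfg)
    write_counts(sim$counts, file.path(outdir, "counts.tsv"))
    write_tsv(sim$samples, file.path(outdir, "samples.tsv"))
    write_tsv(sim$truth, file.path(outdir, "truth_genes.tsv"))
    sim
  })

  th_args <- cfg_list$thresholds
  thresholds <- call_thresholds(
    lfc_min = if (is.null(th_args$lfc_min)) 1 else th_args$lfc_min,
    p_max = th_args$p_max,
    padj_max = if (is.null(th_args$padj_max) && is.null(th_args$p_max))
      0.05 else th_args$padj_max
  )
  fit <- stage("de", {
    fit <- isg_fit(sim$counts, sim$samples, thresholds)
    for (nm in names(fit$results))
      write_tsv(as.data.frame(fit$results[[nm]]),
                file.path(outdir, paste0("contrast_", nm, ".tsv")))
    fit
  })

  prom <- stage("promoters", {
    prom <- simulate_promoters(scfg, sim$truth)
    write_fasta(prom$sequences, file.path(outdir, "promoters.fasta"))
    write_tsv(prom$tss, file.path(outdir, "tss.tsv"))
    prom
  })

  motif_th <- if (is.null(cfg_list$motifs$threshold)) 0.8
              else cfg_list$motifs$threshold
  motifs <- default_motifs(threshold = motif_th)
  scan <- stage("scan", {
    hits <- scan_sequences(motifs[c("ISRE", "GAS")], prom$sequences)
    write_tsv(hits, file.path(outdir, "promoter_hits.tsv"))
    hits
  })
  gene_regions <- data.frame(gene = names(prom$sequences),
                             seq_id = names(prom$sequences))
  presence <- motif_presence(scan, gene_regions)

  rep_frac <- if (is.null(cfg_list$reference$reported_fraction)) 0.43
              else cfg_list$reference$reported_fraction
  fit <- stage("classify", {
    known <- simulate_known_isg_reference(sim$truth, rep_frac,
                                          seed = scfg$seed)
    write_gene_list(known, file.path(outdir, "known_isgs.txt"))
    fit <- classify_isgs(fit, known, presence)
    write_tsv(fit$classification, file.path(outdir, "classification.tsv"))
    fit
  })
  report <- classification_report(fit$classification)

  pk_args <- cfg_list$peaks
  cutoff <- if (is.null(pk_args$proximal_cutoff)) 3000
            else pk_args$proximal_cutoff
  enr <- stage("peaks", {
    pk <- simulate_peaks(scfg)
    write_bed(pk$peaks, file.path(outdir, "peaks.bed"))
    write_counts(pk$counts, file.path(outdir, "peak_counts.tsv"))
    ann <- annotate_tss_distance(pk$peaks, pk$tss)
    write_tsv(ann, file.path(outdir, "peaks_annotated.tsv"))
    sets <- split_proximal_distal(ann, cutoff = cutoff)
    diff <- differential_peaks(
      pk$counts[sets$distal$id, , drop = FALSE], pk$samples,
      rev(unique(pk$samples$condition)),
      fc_min = if (is.null(pk_args$fc_min)) 2 else pk_args$fc_min,
      padj_max = if (is.null(pk_args$padj_max)) 0.05 else pk_args$padj_max)
    write_tsv(as.data.frame(diff),
              file.path(outdir, "differential_peaks.tsv"))
    reg <- regions_to_enrichment(diff, pk$peaks, pk$sequences,
                                 direction = if (is.null(pk_args$direction))
                                   "up" else pk_args$direction)
    if (!length(reg$foreground)) {
      NULL
    } else {
      peak_hits <- scan_sequences(motifs, reg$sequences)
      enr <- hypergeometric_enrichment(reg$foreground, reg$background,
                                       peak_hits,
                                       motif_names = names(motifs))
      write_tsv(enr, file.path(outdir, "motif_enrichment.tsv"))
      enr
    }
  })

  stage("report", {
    classification_report_json(report, file.path(outdir, "report.json"))
    manifest <- list(
      seed = scfg$seed,
      parameters = list(
        thresholds = unclass(thresholds),
        reported_fraction = rep_frac,
        motif_threshold = motif_th,
        proximal_cutoff = cutoff,
        simulate = lapply(unclass(scfg), function(x)
          if (is.function(x)) NULL else x)
      ),
      outputs = {
        files <- setdiff(list.files(outdir), c("manifest.json"))
        lapply(setNames(files, files), function(f)
          unname(tools::md5sum(file.path(outdir, f))))
      },
      package_version = as.character(utils::packageVersion("isgland"))
    )
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               file.path(outdir, "manifest.json"))
  })
  invisible(list(fit = fit, report = report, enrichment = enr,
                 manifest = file.path(outdir, "manifest.json")))
}
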