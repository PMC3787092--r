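# helpers turning YAML blocks into the package's plain data.frames
config_svs <- function(lst, origin) {
  if (is.null(lst) || !length(lst)) return(NULL)
  do.call(rbind, lapply(lst, function(e)
    sv_event(sv_type = e$sv_type, chrom1 = e$chrom1, pos1 = e$pos1,
             chrom2 = if (is.null(e$chrom2)) e$chrom1 else e$chrom2,
             pos2 = if (is.null(e$pos2)) e$pos1 else e$pos2,
             size = if (is.null(e$size)) NA else e$size,
             zygosity = if (is.null(e$zygosity)) "heterozygous" else e$zygosity,
             origin = origin)))
}

config_cn <- function(lst) {
  if (is.null(lst) || !length(lst)) return(NULL)
  do.call(rbind, lapply(lst, function(s)
    cn_segment(s$chrom, s$start, s$end, s$copy_number)))
}

#' Run the full analysis pipeline from a YAML configuration
#'
#' Orchestrates every stage on a synthetic scenario: simulate tumor,
#' matched control, control panel and cfDNA pair sets with the configured
#' aberrations; depth-of-coverage CNV analysis; PEM structural-variant
#' detection with the two-stage window-filter cascade; digital-PCR
#' deletion/amplification calls and cfDNA breakpoint-fraction monitoring;
#' tile Z-scores with tumor-cfDNA concordance; and the cohort report
#' tables. All standard-format outputs (BED, BEDPE, TSV, CSV, JSON) are
#' written under `out_dir`; only `run_log.txt` carries a timestamp, so two
#' runs with the same seed are otherwise byte-identical.
#'
#' @param config Path to a YAML file or an equivalent nested list; see
#'   `system.file("extdata", "demo_config.yaml", package = "svcnv")`.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("seed", "genome", "library", "pem", "cfdna"))
    if (is.null(config[[field]]))
      stop("config is missing required block: ", field)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- c(sprintf("svcnv %s", as.character(utils::packageVersion("svcnv"))),
                 sprintf("started: %s", format(Sys.time())),
                 sprintf("seed: %d", seed))

  genome <- genome_spec(paste0("chr", seq_len(config$genome$n_chromosomes)),
                        rep(config$genome$chromosome_length,
                            config$genome$n_chromosomes))
  lib <- config$library
  somatic_cn <- config_cn(config$somatic_cn)
  somatic_svs <- config_svs(config$somatic_svs, "somatic")
  germline_svs <- config_svs(config$germline_svs, "germline")
  tumor_events <- rbind(somatic_svs, germline_svs)

  plan_for <- function(seed_offset, purity = 1)
    library_plan(lib$insert_mean, lib$insert_sd, lib$read_length,
                 lib$n_pairs, purity, seed + seed_offset)

  # --- simulate ------------------------------------------------------
  tumor <- simulate_read_pairs(genome, plan_for(1, lib$purity),
                               cn = somatic_cn, svs = tumor_events,
                               sample_id = "tumor")
  matched <- simulate_read_pairs(genome, plan_for(2), svs = germline_svs,
                                 sample_id = "matched_control")
  n_panel <- if (is.null(config$n_panel_controls)) 5
             else config$n_panel_controls
  panel <- lapply(seq_len(n_panel), function(i)
    simulate_read_pairs(genome, plan_for(10 + i), svs = germline_svs,
                        sample_id = paste0("panel_", i)))
  cf <- config$cfdna
  cfdna <- mix_cfdna(tumor, matched, cf$tumor_fraction, cf$n_pairs,
                     seed = seed + 3, sample_id = "cfdna")
  if (isTRUE(config$write_pairs)) {
    all_samples <- c(list(tumor, matched, cfdna), panel)
    for (p in all_samples)
      write_pairs(p, file.path(out_dir, paste0(p$sample_id[1], ".pairs.tsv")))
  }
  if (!is.null(somatic_svs))
    write_truth_bedpe(tumor_events, file.path(out_dir, "truth_svs.bedpe"))
  if (!is.null(somatic_cn))
    write_truth_bed(somatic_cn, file.path(out_dir, "truth_cn.bed"))

  # --- depth-of-coverage CNV ----------------------------------------
  dc <- config$doc
  cfg <- doc_config(dc$p_prime, dc$r_prime, dc$window_multiplier,
                    dc$step_fraction, dc$kernel_bandwidth, dc$bh_alpha)
  doc <- run_doc_cnv(tumor, matched, genome, cfg)
  win <- doc$windows
  utils::write.table(
    data.frame(chrom = win$chrom, start = win$start, end = win$end,
               name = sprintf("win_%05d", seq_len(nrow(win))),
               log2_ratio = win$log2_ratio, strand = ".",
               p_value = win$p_value, smoothed = win$smoothed_ratio,
               significant = win$significant),
    file.path(out_dir, "doc_windows.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(doc$regions, file.path(out_dir, "doc_regions.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(window = doc$window, min_window = doc$min_window,
         limits = doc$limits),
    file.path(out_dir, "doc_limits.json"), auto_unbox = TRUE, digits = NA)
  log_lines <- c(log_lines, sprintf("doc window: %d bp", doc$window))

  # --- PEM SV detection + germline cascade --------------------------
  pem <- config$pem
  rl <- lib$read_length
  tumor_calls <- detect_svs(tumor, pem$min_support_tumor,
                            read_length = rl)
  matched_calls <- detect_svs(matched, pem$min_support_control,
                              read_length = rl)
  panel_calls <- lapply(panel, detect_svs,
                        min_support = pem$min_support_control,
                        read_length = rl)
  cascade <- filter_cascade(tumor_calls, matched_calls, panel_calls,
                            window = pem$filter_window)
  write_bedpe(tumor_calls, file.path(out_dir, "tumor_calls_raw.bedpe"))
  write_bedpe(cascade$retained, file.path(out_dir, "tumor_calls_filtered.bedpe"))
  utils::write.table(cascade$removal_log,
                     file.path(out_dir, "removal_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    cascade[c("n_input", "n_after_wf1", "n_after_wf2",
              "pct_after_wf1", "pct_after_wf2")],
    file.path(out_dir, "filter_cascade.json"), auto_unbox = TRUE,
    digits = NA)

  # --- digital PCR ---------------------------------------------------
  dd <- config$ddpcr
  ddpcr_rows <- NULL
  ddpcr_calls <- list()
  if (!is.null(dd)) {
    del_t <- simulate_droplets(droplet_plan(dd$n_partitions,
                                            dd$lambda_deletion_tumor,
                                            dd$lambda_ref, seed + 4),
                               "deletion_assay", "tumor")
    del_n <- simulate_droplets(droplet_plan(dd$n_partitions,
                                            dd$lambda_deletion_normal,
                                            dd$lambda_ref, seed + 5),
                               "deletion_assay", "matched_control")
    her2_t <- simulate_droplets(droplet_plan(dd$n_partitions,
                                             dd$lambda_her2_tumor,
                                             dd$lambda_ref, seed + 6),
                                "her2_assay", "tumor")
    her2_n <- simulate_droplets(droplet_plan(dd$n_partitions,
                                             dd$lambda_her2_normal,
                                             dd$lambda_ref, seed + 7),
                                "her2_assay", "matched_control")
    counts <- rbind(del_t, del_n, her2_t, her2_n)
    ddpcr_rows <- quantify_ddpcr(counts)
    q <- function(assay, sample) {
      r <- ddpcr_rows[ddpcr_rows$assay_id == assay &
                        ddpcr_rows$sample_id == sample, ]
      structure(as.list(r), class = "quant_result")
    }
    ddpcr_calls$deletion <- call_deletion(q("deletion_assay", "tumor"),
                                          q("deletion_assay", "matched_control"))
    ddpcr_calls$her2 <- call_her2_amplification(q("her2_assay", "tumor"),
                                                q("her2_assay", "matched_control"))
    utils::write.table(ddpcr_rows, file.path(out_dir, "ddpcr_quant.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  wl <- config$wells
  bp_frac <- NULL
  if (!is.null(wl)) {
    plate <- simulate_well_plate(wl$breakpoint_fraction, wl$wells_per_assay,
                                 wl$genome_equivalents_per_well, seed + 8)
    bp_frac <- breakpoint_fraction(plate$breakpoint, plate$reference)
  }
  jsonlite::write_json(c(ddpcr_calls, list(breakpoint_fraction = bp_frac)),
                       file.path(out_dir, "ddpcr_calls.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- cfDNA Z-scores ------------------------------------------------
  tile <- if (is.null(config$zscore)) 5e6 else config$zscore$tile
  ctrl_tracks <- lapply(panel, function(p)
    normalize_counts(tile_counts(p, genome, tile)))
  tumor_track <- zscores(normalize_counts(tile_counts(tumor, genome, tile)),
                         ctrl_tracks)
  cfdna_track <- zscores(normalize_counts(tile_counts(cfdna, genome, tile)),
                         ctrl_tracks)
  utils::write.table(tumor_track, file.path(out_dir, "zscore_tumor.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cfdna_track, file.path(out_dir, "zscore_cfdna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  concordance <- tryCatch(
    region_restricted_correlation(tumor_track, cfdna_track, doc$regions,
                                  "amplified"),
    error = function(e) list(region_class = "amplified", error = conditionMessage(e)))
  jsonlite::write_json(concordance, file.path(out_dir, "concordance.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- report --------------------------------------------------------
  counts_tab <- tabulate_sv_counts(cascade$retained,
                                   samples = unique(tumor$sample_id))
  prev <- summarize_prevalence(counts_tab)
  utils::write.table(counts_tab, file.path(out_dir, "sv_counts.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(prev, file.path(out_dir, "sv_prevalence.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(genome = genome, doc = doc, tumor_calls = tumor_calls,
                 cascade = cascade, ddpcr = ddpcr_rows,
                 ddpcr_calls = ddpcr_calls, breakpoint_fraction = bp_frac,
                 tumor_track = tumor_track, cfdna_track = cfdna_track,
                 concordance = concordance, sv_counts = counts_tab,
                 prevalence = prev))
}
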