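#' Pipeline configuration
#'
#' All tunables of the detection pipeline with their defaults. Each
#' default is either a workflow threshold (bin width 1 kb, 500 minimum
#' occupancy events, 90% bin-occupancy cap, q = 50 segment members,
#' promoter flank 3 kb, topic numbers 2..10, component z threshold 1.3,
#' 80% positive-bin fraction, >= 3 components, >= 200 positive bins,
#' per-feature AUROC > 0.6, top-three mean AUROC > 0.65, >= 3 passing
#' features, dedup Jaccard 0.25) or a documented sampler convention
#' (alpha = 50/k, beta = 0.01, 500 Gibbs sweeps).
#'
#' @param ... overrides for any field.
#' @return a `RunConfig` list.
#' @export
condsig_config <- function(...) {
  cfg <- list(bin_width = 1000,
              min_events = 500,
              max_frac = 0.9,
              q = 50,
              promoter_flank = 3000,
              k_range = 2:10,
              alpha_topic = NULL,   # NULL -> 50/k
              beta_word = 0.01,
              n_iter = 500,
              lambda_z = 1.3,
              pos_frac = 0.8,
              min_components = 3,
              min_positive = 200,
              auroc_min = 0.6,
              mean_top3_min = 0.65,
              min_passing = 3,
              dedup_jaccard = 0.25,
              reps = 1,
              seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "RunConfig")
}

#' Detect co-occupancy signatures (steps 1-2)
#'
#' Runs segmentation (one iteration per retained CAP as focus), the
#' promoter / non-promoter context split, biterm-topic-model fitting with
#' automatic topic-number selection, and signature calling. Condensation
#' scoring is a separate phase ([score_signatures()]) so the same fits can
#' be scored under different annotation sets.
#'
#' The global seed fans out deterministically to per-(focus, context, k)
#' sampler seeds, so results do not depend on evaluation order.
#'
#' @param occ a filtered `OccupancyMatrix`.
#' @param promoter_map logical promoter flag per occupancy row.
#' @param config a [condsig_config()].
#' @return list with `signatures` (list of `Signature`), `selection`
#'   (data.frame of per-segment model-selection reports) and `segments`
#'   (per-focus member tables).
#' @export
detect_signatures <- function(occ, promoter_map, config = condsig_config()) {
  stopifnot(inherits(occ, "OccupancyMatrix"),
            length(promoter_map) == nrow(occ$O))
  signatures <- list()
  sel_rows <- list()
  seg_rows <- list()
  for (focus in occ$caps) {
    seg <- build_segment(occ, focus, q = config$q)
    if (is.null(seg)) next
    seg_rows[[focus]] <- data.frame(focus = focus, cap = seg$members,
                                    beta = unname(seg$beta),
                                    gamma = unname(seg$gamma))
    for (ctx_seg in split_context(seg, promoter_map)) {
      corpus <- corpus_from_segment(ctx_seg, occ)
      if (nrow(corpus$biterms) == 0) {
        message("focus '", focus, "' ", ctx_seg$context,
                ": no biterms; skipped")
        next
      }
      seed_fn <- local({
        f <- focus; cx <- ctx_seg$context; s <- config$seed
        function(k, rep) segment_seed(s + (rep - 1L), f, cx, k)
      })
      sel <- select_topic_number(corpus, k_range = config$k_range,
                                 reps = config$reps,
                                 alpha_topic = config$alpha_topic,
                                 beta_word = config$beta_word,
                                 n_iter = config$n_iter,
                                 seed_fn = seed_fn)
      rep_df <- sel$report
      rep_df$focus <- focus
      rep_df$context <- ctx_seg$context
      sel_rows[[paste(focus, ctx_seg$context)]] <- rep_df
      sigs <- call_signatures(sel$model, corpus, ctx_seg, occ,
                              lambda_z = config$lambda_z,
                              pos_frac = config$pos_frac,
                              min_components = config$min_components,
                              min_positive = config$min_positive)
      signatures <- c(signatures, sigs)
    }
  }
  list(signatures = signatures,
       selection = if (length(sel_rows) > 0) do.call(rbind, sel_rows)
                   else NULL,
       segments = if (length(seg_rows) > 0) do.call(rbind, seg_rows)
                  else NULL)
}

#' Score signatures and assemble final CondSigs (step 3)
#'
#' Computes condensation-feature AUROCs for every signature, filters to
#' CondSigs and removes redundant ones.
#'
#' @param detection output of [detect_signatures()].
#' @param occ the filtered `OccupancyMatrix`.
#' @param annotations a `CapAnnotations`.
#' @param promoter_map logical promoter flag per occupancy row.
#' @param rbs optional per-bin RNA-binding-strength signal; when absent
#'   the pipeline proceeds with the five annotation features.
#' @param config a [condsig_config()].
#' @return list with `condsigs` (final deduplicated list), `scored` (all
#'   scored signatures) and `table` (summary data.frame).
#' @export
score_condsigs <- function(detection, occ, annotations, promoter_map,
                           rbs = NULL, config = condsig_config()) {
  scored <- score_signatures(detection$signatures, occ, annotations,
                             promoter_map, rbs = rbs,
                             auroc_min = config$auroc_min,
                             mean_top3_min = config$mean_top3_min,
                             min_passing = config$min_passing,
                             pos_frac = config$pos_frac)
  passing <- Filter(function(cs) cs$is_condsig, scored)
  final <- deduplicate(passing, dedup_jaccard = config$dedup_jaccard)
  list(condsigs = final, scored = scored, table = condsig_table(final))
}

# Summary table of final CondSigs.
condsig_table <- function(condsigs) {
  if (length(condsigs) == 0)
    return(data.frame(id = character(0), context = character(0),
                      focus = character(0), n_components = integer(0),
                      components = character(0), z_scores = character(0),
                      n_positive = integer(0), mean_top3 = numeric(0)))
  rows <- lapply(condsigs, function(cs) {
    aur <- cs$aurocs
    df <- data.frame(id = cs$id, context = cs$context, focus = cs$focus,
                     n_components = length(cs$components),
                     components = paste(cs$components, collapse = ";"),
                     z_scores = paste(sprintf("%.4f", cs$z_scores),
                                      collapse = ";"),
                     n_positive = length(cs$pos_bins),
                     mean_top3 = round(cs$mean_top3, 6))
    for (ft in names(aur)) df[[paste0("auroc_", ft)]] <- round(aur[[ft]], 6)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full detection pipeline
#'
#' End-to-end composition: occupancy matrix construction and filtering,
#' segmentation, context split, topic modelling with topic-number
#' selection, signature calling, condensation-feature AUROC filtration
#' and redundancy removal. Accepts either in-memory objects or file
#' paths; when `out_dir` is given, writes `condsigs.tsv`,
#' `positive_sites.bed`, per-CondSig positive-bin BEDs, the
#' model-selection report and a config echo.
#'
#' @param peaks named list of GRanges, or a directory of `<CAP>.bed`
#'   files.
#' @param chrom_sizes named vector or chrom.sizes path.
#' @param genes gene annotation data.frame or BED6 path.
#' @param annotations `CapAnnotations`, or an annotation TSV path.
#' @param ppi optional PPI TSV path (ignored when `annotations` is
#'   already a `CapAnnotations`).
#' @param blacklist optional GRanges or BED path.
#' @param rbs optional per-bin signal vector or bedGraph path.
#' @param config a [condsig_config()].
#' @param out_dir optional output directory.
#' @return list with `condsigs`, `table`, `sites` (merged positive-site
#'   GRanges), `scored`, `selection`, `occupancy`, `promoter_map` and
#'   `config`.
#' @export
condsig_detect <- function(peaks, chrom_sizes, genes, annotations,
                           ppi = NULL, blacklist = NULL, rbs = NULL,
                           config = condsig_config(), out_dir = NULL) {
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  binning <- genome_binning(chrom_sizes, config$bin_width)
  if (is.character(peaks)) {
    files <- list.files(peaks, pattern = "\\.bed$", full.names = TRUE)
    if (length(files) == 0) stop("no .bed files in peaks directory ", peaks)
    caps <- sub("\\.bed$", "", basename(files))
    peaks <- stats::setNames(lapply(files, read_bed, chrom_sizes = chrom_sizes),
                             caps)
  }
  if (is.character(blacklist)) blacklist <- read_bed(blacklist, chrom_sizes)
  if (is.character(rbs)) rbs <- read_signal_bedgraph(rbs, binning)
  if (!inherits(annotations, "CapAnnotations"))
    annotations <- read_cap_annotations(annotations, ppi, names(peaks))
  if (is.null(rbs))
    message("no RNA-binding-strength track; proceeding with 5 features")

  occ <- build_occupancy_matrix(binning, peaks)
  occ <- filter_matrix(occ, blacklist = blacklist,
                       min_events = config$min_events,
                       max_frac = config$max_frac)
  promoter_all <- promoters_from_genes(genes, binning,
                                       flank = config$promoter_flank)
  promoter_map <- promoter_all[occ$bin_index]

  detection <- detect_signatures(occ, promoter_map, config)
  scored <- score_condsigs(detection, occ, annotations, promoter_map,
                           rbs = rbs, config = config)
  sites <- positive_sites(scored$condsigs, occ)
  result <- list(condsigs = scored$condsigs, table = scored$table,
                 sites = sites, scored = scored$scored,
                 selection = detection$selection, occupancy = occ,
                 promoter_map = promoter_map, config = config)
  if (!is.null(out_dir)) write_detection(result, out_dir)
  result
}

# Write the detection outputs (stable formatting for reproducibility).
write_detection <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$table, file.path(out_dir, "condsigs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(result$sites, file.path(out_dir, "positive_sites.bed"))
  dir.create(file.path(out_dir, "condsig_bins"), showWarnings = FALSE)
  for (cs in result$condsigs) {
    gr <- result$occupancy$binning$gr[
      result$occupancy$bin_index[sort(cs$pos_bins)]]
    write_bed(gr, file.path(out_dir, "condsig_bins",
                            paste0(gsub("[^A-Za-z0-9._-]", "_", cs$id), ".bed")))
  }
  if (!is.null(result$selection))
    utils::write.table(result$selection,
                       file.path(out_dir, "model_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- result$config
  cfg$k_range <- paste(range(cfg$k_range), collapse = ":")
  cfg$alpha_topic <- cfg$alpha_topic %||% "50/k"
  writeLines(paste0(names(cfg), "\t", vapply(cfg, paste, character(1),
                                             collapse = ",")),
             file.path(out_dir, "config_echo.tsv"))
  invisible(out_dir)
}

#' Post-process detection outputs for one component CAP
#'
#' Classifies the CAP's peaks against the positive sites of the CondSigs
#' containing it, optionally refines the classification, and merges peaks
#' into domains.
#'
#' @param cap CAP name.
#' @param peaks GRanges of the CAP's peaks.
#' @param condsigs final CondSig list from [condsig_detect()].
#' @param occ the `OccupancyMatrix` from the detection result.
#' @param refine `"none"`, `"atac"` or `"cap-count"`.
#' @param atac_peaks GRanges of ATAC peaks (for `refine = "atac"`).
#' @param min_caps threshold for `refine = "cap-count"` (default 10).
#' @param gap_kb domain merge gap in kb (default 5; use 10 for broad-peak
#'   CAPs).
#' @return list with `classification` and `domains`.
#' @export
condsig_postprocess <- function(cap, peaks, condsigs, occ,
                                refine = "none", atac_peaks = NULL,
                                min_caps = 10, gap_kb = 5) {
  with_cap <- Filter(function(cs) cap %in% cs$components, condsigs)
  sites <- positive_sites(with_cap, occ)
  cls <- classify_peaks(cap, peaks, sites)
  if (refine != "none")
    cls <- refine_classification(cls, mode = refine, atac_peaks = atac_peaks,
                                 occ = occ, min_caps = min_caps)
  list(classification = cls, domains = peaks_to_domains(cls, gap_kb = gap_kb))
}
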