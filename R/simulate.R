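#' Configuration for a synthetic CondSig dataset
#'
#' Defines the generative model used for end-to-end validation: a small
#' genome of 1 kb bins with a promoter stratum, sparse i.i.d. background
#' occupancy, planted co-occupancy signatures whose component CAPs jointly
#' occupy a dedicated set of context-matched bins, condensation
#' annotations enriched among planted components, within-signature PPI
#' edges, and an RNA-binding-strength track elevated at planted bins.
#'
#' @param seed integer seed.
#' @param chrom_sizes named vector (default one 5 Mb chromosome).
#' @param bin_width bin width (default 1000).
#' @param n_caps number of CAPs (default 30).
#' @param promoter_fraction fraction of bins flagged promoter
#'   (default 0.4).
#' @param signatures list of planted signatures; each a list with
#'   `components` (CAP names), `n_bins`, `prob` (co-occupancy
#'   probability), `context` (`"promoter"` or `"non-promoter"`). Default:
#'   3 signatures of 5 CAPs x 500 bins at probability 0.9, contexts
#'   promoter / non-promoter / non-promoter; the two non-promoter
#'   signatures share 2 components, emulating the component sharing
#'   observed among real chromatin-condensate signatures.
#' @param background_rate i.i.d. background occupancy probability per
#'   (bin, CAP) (default 0.05).
#' @param annotation_enrich probability a planted component carries each
#'   condensation annotation (default 0.8).
#' @param annotation_background same for non-component CAPs
#'   (default 0.1).
#' @param rbs_background,rbs_planted exponential mean of the
#'   RNA-binding-strength signal at background vs planted bins
#'   (defaults 0.5 and 2).
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1,
                              chrom_sizes = c(chrS = 5e6),
                              bin_width = 1000,
                              n_caps = 30,
                              promoter_fraction = 0.4,
                              signatures = NULL,
                              background_rate = 0.05,
                              annotation_enrich = 0.8,
                              annotation_background = 0.1,
                              rbs_background = 0.5,
                              rbs_planted = 2) {
  caps <- sprintf("CAP%02d", seq_len(n_caps))
  if (is.null(signatures)) {
    comp_sets <- list(caps[1:5], caps[6:10], caps[9:13])
    ctxs <- c("promoter", "non-promoter", "non-promoter")
    signatures <- lapply(1:3, function(s)
      list(components = comp_sets[[s]],
           n_bins = 500, prob = 0.9, context = ctxs[[s]]))
  }
  for (sg in signatures) {
    if (!all(sg$components %in% caps))
      stop("planted components exceed the configured CAP set")
    stopifnot(sg$prob >= 0, sg$prob <= 1,
              sg$context %in% c("promoter", "non-promoter"))
  }
  structure(list(seed = seed, chrom_sizes = chrom_sizes,
                 bin_width = bin_width, caps = caps,
                 promoter_fraction = promoter_fraction,
                 signatures = signatures,
                 background_rate = background_rate,
                 annotation_enrich = annotation_enrich,
                 annotation_background = annotation_background,
                 rbs_background = rbs_background,
                 rbs_planted = rbs_planted),
            class = "SimulationConfig")
}

#' Simulate a synthetic CondSig dataset
#'
#' Draws occupancy, annotations, PPI edges, gene (promoter) structure and
#' an RNA-binding-strength track under [simulation_config()], returning
#' in-memory objects plus ground truth; optionally writes a ready-to-run
#' input directory (per-CAP peak BEDs, annotation and PPI TSVs, RBS
#' bedGraph, gene BED, chrom.sizes, ground_truth.json). Deterministic
#' under the config seed.
#'
#' @param config a `SimulationConfig`.
#' @param out_dir optional output directory.
#' @return list with `binning`, `peaks` (named list of GRanges),
#'   `promoter_map` (logical per bin), `genes` (data.frame),
#'   `annotations` (`CapAnnotations`), `rbs` (per-bin signal),
#'   `ground_truth` (per-signature component sets, planted bin GRanges and
#'   per-CAP annotation truth) and `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  binning <- genome_binning(config$chrom_sizes, config$bin_width)
  n <- binning$n_bins
  caps <- config$caps
  m <- length(caps)

  # Promoter stratum from synthetic genes: promoters tile the genome at
  # regular spacing so that TSS +/- 3 kb flags ~promoter_fraction of bins.
  flank <- 3000
  prom_bins_per_gene <- ceiling(2 * flank / config$bin_width) + 1
  n_genes <- max(1, round(config$promoter_fraction * n / prom_bins_per_gene))
  spacing <- floor(n / n_genes)
  gene_bins <- seq(4, by = spacing, length.out = n_genes)
  tss <- (gene_bins - 1) * config$bin_width + 500
  genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(binning$gr[gene_bins])),
                      start = tss, end = tss + 2000,
                      name = sprintf("gene%04d", seq_len(n_genes)),
                      score = 0, strand = "+",
                      stringsAsFactors = FALSE)
  promoter_map <- promoters_from_genes(genes, binning, flank = flank)

  # occupancy: background + planted signatures
  occ_mat <- matrix(stats::rbinom(n * m, 1, config$background_rate), n, m,
                    dimnames = list(NULL, caps))
  pool <- list("promoter" = which(promoter_map),
               "non-promoter" = which(!promoter_map))
  truth <- list()
  for (s in seq_along(config$signatures)) {
    sg <- config$signatures[[s]]
    avail <- pool[[sg$context]]
    if (length(avail) < sg$n_bins)
      stop("not enough ", sg$context, " bins to plant signature ", s)
    planted <- sort(sample(avail, sg$n_bins))
    pool[[sg$context]] <- setdiff(avail, planted)  # signatures get disjoint bins
    for (cp in sg$components)
      occ_mat[planted, cp] <- pmax(occ_mat[planted, cp],
                                   stats::rbinom(sg$n_bins, 1, sg$prob))
    truth[[s]] <- list(components = sg$components,
                       bins = planted,
                       context = sg$context)
  }

  peaks <- lapply(caps, function(cp) {
    rows <- which(occ_mat[, cp] == 1)
    if (length(rows) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(binning$gr[rows])
  })
  names(peaks) <- caps

  # condensation annotations: enriched among planted components
  comp_caps <- unique(unlist(lapply(config$signatures, `[[`, "components")))
  p_ann <- ifelse(caps %in% comp_caps, config$annotation_enrich,
                  config$annotation_background)
  draw_flag <- function() stats::rbinom(m, 1, p_ann) == 1
  llps <- draw_flag(); idr <- draw_flag(); rbp <- draw_flag()
  mlo <- stats::setNames(vector("list", m), caps)
  mlo[] <- list(character(0))
  for (s in seq_along(config$signatures)) {
    sg <- config$signatures[[s]]
    in_mlo <- sg$components[stats::rbinom(length(sg$components), 1,
                                          config$annotation_enrich) == 1]
    for (cp in in_mlo) mlo[[cp]] <- c(mlo[[cp]], sprintf("MLO%d", s))
  }
  bg_caps <- setdiff(caps, comp_caps)
  in_bg_mlo <- bg_caps[stats::rbinom(length(bg_caps), 1,
                                     config$annotation_background) == 1]
  for (cp in in_bg_mlo) mlo[[cp]] <- c(mlo[[cp]], "MLO_bg")
  ppi <- list()
  for (s in seq_along(config$signatures)) {
    prs <- utils::combn(config$signatures[[s]]$components, 2)
    sel <- stats::rbinom(ncol(prs), 1, config$annotation_enrich) == 1
    if (any(sel)) ppi[[length(ppi) + 1]] <- t(prs[, sel, drop = FALSE])
  }
  other_prs <- utils::combn(caps, 2)
  planted_keys <- if (length(ppi) > 0) {
    pp <- do.call(rbind, ppi); ppi_pair_key(pp[, 1], pp[, 2])
  } else character(0)
  within_sig <- ppi_pair_key(other_prs[1, ], other_prs[2, ]) %in%
    unlist(lapply(config$signatures, function(sg)
      ppi_pair_key(utils::combn(sg$components, 2)[1, ],
                   utils::combn(sg$components, 2)[2, ])))
  bg_candidates <- other_prs[, !within_sig, drop = FALSE]
  sel_bg <- stats::rbinom(ncol(bg_candidates), 1,
                          config$annotation_background) == 1
  if (any(sel_bg)) ppi[[length(ppi) + 1]] <- t(bg_candidates[, sel_bg, drop = FALSE])
  ppi_df <- if (length(ppi) > 0) {
    pm <- unique(do.call(rbind, ppi))
    data.frame(cap_a = pmin(pm[, 1], pm[, 2]), cap_b = pmax(pm[, 1], pm[, 2]),
               stringsAsFactors = FALSE)
  } else data.frame(cap_a = character(0), cap_b = character(0))

  # phase-separation scores: components near (0.8, 0.8), background low
  jitter01 <- function(center) pmin(1, pmax(0, center + stats::rnorm(m, 0, 0.08)))
  ps_self <- ifelse(caps %in% comp_caps, jitter01(0.8), jitter01(0.3))
  ps_part <- ifelse(caps %in% comp_caps, jitter01(0.8), jitter01(0.3))

  ann_df <- data.frame(cap = caps,
                       llps = as.integer(llps), idr = as.integer(idr),
                       rbp = as.integer(rbp),
                       mlo = vapply(mlo, paste, character(1), collapse = ","),
                       ps_self = round(ps_self, 4), ps_part = round(ps_part, 4),
                       stringsAsFactors = FALSE)
  annotations <- suppressWarnings(read_cap_annotations(ann_df, ppi_df, caps))

  # RNA-binding-strength: exponential, elevated at planted bins
  rbs <- stats::rexp(n, rate = 1 / config$rbs_background)
  all_planted <- unique(unlist(lapply(truth, `[[`, "bins")))
  rbs[all_planted] <- stats::rexp(length(all_planted),
                                  rate = 1 / config$rbs_planted)
  rbs <- round(rbs, 4)

  ground_truth <- list(signatures = lapply(truth, function(tr)
    list(components = tr$components, context = tr$context,
         bins = tr$bins,
         sites = GenomicRanges::reduce(binning$gr[tr$bins]))),
    annotations = ann_df)

  sim <- list(binning = binning, peaks = peaks, promoter_map = promoter_map,
              genes = genes, annotations = annotations, ppi = ppi_df,
              rbs = rbs, ground_truth = ground_truth, config = config)
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

# Emit a simulated dataset as a ready-to-run input directory.
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  for (cp in names(sim$peaks))
    write_bed(sim$peaks[[cp]], file.path(out_dir, "peaks", paste0(cp, ".bed")))
  cs <- data.frame(chrom = names(sim$config$chrom_sizes),
                   size = unname(sim$config$chrom_sizes))
  utils::write.table(format(cs, scientific = FALSE, trim = TRUE),
                     file.path(out_dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$genes, file.path(out_dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ann <- sim$ground_truth$annotations
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ppi, file.path(out_dir, "ppi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bg <- data.frame(chrom = as.character(GenomicRanges::seqnames(sim$binning$gr)),
                   start = GenomicRanges::start(sim$binning$gr) - 1L,
                   end = GenomicRanges::end(sim$binning$gr),
                   value = sim$rbs)
  utils::write.table(format(bg, scientific = FALSE, trim = TRUE),
                     file.path(out_dir, "rbs.bedGraph"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  gt <- list(signatures = lapply(sim$ground_truth$signatures, function(s)
    list(components = s$components, context = s$context, bins = s$bins)))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Match predicted CondSigs against planted ground truth
#'
#' For each planted signature, reports the best (maximum over predictions)
#' component-set Jaccard index, and the positive-bin recall and precision
#' of that best-matching prediction.
#'
#' @param condsigs list of predicted `CondSig` objects.
#' @param ground_truth the `ground_truth` element of [simulate_dataset()].
#' @param occ the filtered `OccupancyMatrix` used in detection (to map
#'   prediction rows back to genomic bins).
#' @return data.frame with one row per planted signature: `truth`,
#'   `component_jaccard`, `bin_recall`, `bin_precision`, `best_id`.
#' @export
match_signatures <- function(condsigs, ground_truth, occ) {
  rows <- lapply(seq_along(ground_truth$signatures), function(s) {
    tr <- ground_truth$signatures[[s]]
    if (length(condsigs) == 0)
      return(data.frame(truth = s, component_jaccard = 0, bin_recall = 0,
                        bin_precision = 0, best_id = NA_character_))
    jac <- vapply(condsigs, function(cs) jaccard(cs$components, tr$components),
                  numeric(1))
    best <- which.max(jac)
    pred_bins <- occ$bin_index[condsigs[[best]]$pos_bins]
    inter <- length(intersect(pred_bins, tr$bins))
    data.frame(truth = s, component_jaccard = jac[best],
               bin_recall = inter / length(tr$bins),
               bin_precision = if (length(pred_bins) == 0) 0
                               else inter / length(pred_bins),
               best_id = condsigs[[best]]$id)
  })
  do.call(rbind, rows)
}
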