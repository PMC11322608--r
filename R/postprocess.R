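#' Classify a CAP's peaks by CondSig-positive site overlap
#'
#' A peak is CondSig-positive iff it overlaps, by at least 1 bp, any
#' merged positive site of a CondSig in which the CAP is a component;
#' otherwise negative.
#'
#' @param cap CAP name (for messages).
#' @param peaks GRanges of the CAP's peaks.
#' @param positive_sites GRanges of merged positive sites of the CondSigs
#'   containing the CAP (may be empty).
#' @return a `PeakClassification`: list with `cap`, `positive`, `negative`
#'   (GRanges) and `refinement` (initially `"none"`).
#' @export
classify_peaks <- function(cap, peaks, positive_sites) {
  if (length(positive_sites) == 0) {
    warning("CAP '", cap, "' is not a component of any CondSig; ",
            "all peaks classified negative")
    pos <- rep(FALSE, length(peaks))
  } else {
    pos <- IRanges::overlapsAny(peaks, positive_sites, minoverlap = 1L)
  }
  structure(list(cap = cap, positive = peaks[pos], negative = peaks[!pos],
                 refinement = "none"),
            class = "PeakClassification")
}

#' Refine a peak classification for fair comparison
#'
#' Removes, from both classes, peaks that fail a matching criterion:
#' overlap with ATAC-seq peaks (`mode = "atac"`) or overlap with a bin
#' carrying occupancy events of more than `min_caps` CAPs
#' (`mode = "cap-count"`, strict comparison). Refinement never moves a
#' peak between classes.
#'
#' @param classification a `PeakClassification`.
#' @param mode `"atac"` or `"cap-count"`.
#' @param atac_peaks GRanges of ATAC-seq peaks (required for `"atac"`).
#' @param occ an `OccupancyMatrix` (required for `"cap-count"`).
#' @param min_caps occupancy-event threshold (default 10; peaks need a bin
#'   with more than this many occupied CAPs).
#' @return refined `PeakClassification`.
#' @export
refine_classification <- function(classification, mode = c("atac", "cap-count"),
                                  atac_peaks = NULL, occ = NULL, min_caps = 10) {
  mode <- match.arg(mode)
  keep_fun <- if (mode == "atac") {
    if (is.null(atac_peaks)) stop("atac refinement requires atac_peaks")
    function(p) IRanges::overlapsAny(p, atac_peaks, minoverlap = 1L)
  } else {
    if (is.null(occ)) stop("cap-count refinement requires an OccupancyMatrix")
    busy <- occ$binning$gr[occ$bin_index[Matrix::rowSums(occ$O) > min_caps]]
    function(p) IRanges::overlapsAny(p, busy, minoverlap = 1L)
  }
  out <- classification
  out$positive <- classification$positive[keep_fun(classification$positive)]
  out$negative <- classification$negative[keep_fun(classification$negative)]
  out$refinement <- mode
  out
}

#' Merge peaks into domains
#'
#' Single-linkage merge of peaks whose edge-to-edge gap is at most
#' `gap_kb` kilobases (inclusive). A domain is CondSig-positive iff it
#' contains at least one positive peak.
#'
#' @param classification a `PeakClassification`.
#' @param gap_kb maximum merge gap in kb: 5 for narrow-peak CAPs, 10 for
#'   broad-peak CAPs.
#' @return list with `domains` (GRanges), `positive` and `negative`
#'   (GRanges subsets).
#' @export
peaks_to_domains <- function(classification, gap_kb = 5) {
  all_peaks <- c(classification$positive, classification$negative)
  if (length(all_peaks) == 0)
    return(list(domains = GenomicRanges::GRanges(),
                positive = GenomicRanges::GRanges(),
                negative = GenomicRanges::GRanges()))
  domains <- GenomicRanges::reduce(all_peaks, min.gapwidth = gap_kb * 1000 + 1)
  has_pos <- IRanges::overlapsAny(domains, classification$positive,
                                        minoverlap = 1L)
  list(domains = domains, positive = domains[has_pos],
       negative = domains[!has_pos])
}

# Length-weighted mean of a per-bin signal over a set of intervals.
interval_mean_signal <- function(gr, binning, signal) {
  if (length(gr) == 0) return(NA_real_)
  hits <- GenomicRanges::findOverlaps(gr, binning$gr, minoverlap = 1L)
  if (length(hits) == 0) return(0)
  ov <- IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                            binning$gr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  sum(w * signal[S4Vectors::subjectHits(hits)]) / sum(w)
}

#' Extract high-confidence condensate-related sites
#'
#' Keeps a merged CondSig-positive site iff every component CAP of every
#' CondSig assigning the site shows more than `fold` times its
#' CondSig-negative-peak baseline signal at the site (strict comparison).
#' Sites lacking a signal track for a required CAP, or whose required CAP
#' has no negative peaks (undefined baseline), are skipped with a warning.
#'
#' @param condsigs list of final `CondSig` objects.
#' @param occ the `OccupancyMatrix` (bin coordinates).
#' @param signal_tracks named list of per-bin signal vectors (over the
#'   binning), one per component CAP.
#' @param peak_classifications named list of `PeakClassification` objects
#'   per component CAP (provides the negative-peak baselines).
#' @param fold fold-increase threshold (default 1.5).
#' @return GRanges of high-confidence sites (subset of the merged
#'   positive sites).
#' @export
high_confidence_sites <- function(condsigs, occ, signal_tracks,
                                  peak_classifications, fold = 1.5) {
  binning <- occ$binning
  sites <- positive_sites(condsigs, occ)
  if (length(sites) == 0) return(sites)
  persig_sites <- lapply(condsigs, function(cs)
    GenomicRanges::reduce(binning$gr[occ$bin_index[cs$pos_bins]]))
  baseline <- new.env()
  get_baseline <- function(cap) {
    if (!is.null(baseline[[cap]])) return(baseline[[cap]])
    pc <- peak_classifications[[cap]]
    b <- if (is.null(pc) || length(pc$negative) == 0) NA_real_
         else interval_mean_signal(pc$negative, binning, signal_tracks[[cap]])
    baseline[[cap]] <- b
    b
  }
  keep <- logical(length(sites))
  for (i in seq_along(sites)) {
    site <- sites[i]
    assigning <- which(vapply(persig_sites, function(s)
      length(GenomicRanges::findOverlaps(site, s)) > 0, logical(1)))
    req_caps <- unique(unlist(lapply(condsigs[assigning], `[[`, "components")))
    ok <- TRUE
    for (cap in req_caps) {
      if (is.null(signal_tracks[[cap]])) {
        warning("no signal track for component CAP '", cap, "'; site ", i,
                " skipped")
        ok <- FALSE; break
      }
      base <- get_baseline(cap)
      if (is.na(base)) {
        warning("CAP '", cap, "' has no CondSig-negative peaks; site ", i,
                " skipped")
        ok <- FALSE; break
      }
      m <- interval_mean_signal(site, binning, signal_tracks[[cap]])
      if (!(m > fold * base)) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  sites[keep]
}
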