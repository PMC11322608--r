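#' Build the genome-wide binary CAP occupancy matrix
#'
#' `O[i, j] = 1` iff CAP j has at least 1 bp of peak overlap with bin i.
#'
#' @param binning a [genome_binning()] object.
#' @param peaksets named list of GRanges (one per CAP); names are CAP names.
#' @return an `OccupancyMatrix`: list with `binning`, `caps`, sparse 0/1
#'   matrix `O` (bins x CAPs) and `bin_index` (row -> bin of `binning`).
#' @export
build_occupancy_matrix <- function(binning, peaksets) {
  if (length(peaksets) == 0) stop("need at least one PeakSet")
  caps <- names(peaksets)
  if (is.null(caps) || any(!nzchar(caps))) stop("peaksets must be a named list")
  if (anyDuplicated(caps)) stop("duplicate CAP names in peaksets")
  ij <- lapply(seq_along(peaksets), function(j) {
    hits <- GenomicRanges::findOverlaps(binning$gr, peaksets[[j]], minoverlap = 1L)
    i <- unique(S4Vectors::queryHits(hits))
    if (length(i) == 0) return(NULL)
    cbind(i = i, j = j)
  })
  ij <- do.call(rbind, Filter(Negate(is.null), ij))
  if (is.null(ij)) ij <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  O <- Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = 1,
                            dims = c(binning$n_bins, length(caps)),
                            dimnames = list(NULL, caps))
  structure(list(binning = binning, caps = caps, O = O,
                 bin_index = seq_len(binning$n_bins)),
            class = "OccupancyMatrix")
}

#' Filter the occupancy matrix
#'
#' Column-first filtering: CAPs with fewer than `min_events` occupancy
#' events are dropped first; then bins occupied by more than `max_frac`
#' of the retained CAPs are dropped (sequencing-bias guard), as are bins
#' overlapping the blacklist. Both comparisons are strict; the
#' occupied-fraction denominator is the number of retained CAPs.
#'
#' @param occ an `OccupancyMatrix`.
#' @param blacklist optional GRanges of blacklisted regions.
#' @param min_events minimum occupancy events per CAP (default 500).
#' @param max_frac maximum occupied fraction per bin (default 0.9).
#' @return filtered `OccupancyMatrix` with updated `bin_index`.
#' @export
filter_matrix <- function(occ, blacklist = NULL, min_events = 500, max_frac = 0.9) {
  stopifnot(inherits(occ, "OccupancyMatrix"))
  keep_cap <- Matrix::colSums(occ$O) >= min_events
  if (!any(keep_cap)) stop("no qualifying CAPs after the min_events filter")
  O <- occ$O[, keep_cap, drop = FALSE]
  keep_bin <- Matrix::rowSums(O) / ncol(O) <= max_frac
  if (!is.null(blacklist) && length(blacklist) > 0) {
    keep_bin <- keep_bin & !IRanges::overlapsAny(
      occ$binning$gr[occ$bin_index], blacklist, minoverlap = 1L)
  }
  structure(list(binning = occ$binning,
                 caps = occ$caps[keep_cap],
                 O = O[keep_bin, , drop = FALSE],
                 bin_index = occ$bin_index[keep_bin]),
            class = "OccupancyMatrix")
}

#' Export the occupancy matrix as sparse triplets
#'
#' Debug helper: writes one `(bin_id, cap, 1)` row per occupancy event.
#'
#' @param occ an `OccupancyMatrix`.
#' @param path output TSV path.
#' @export
write_occupancy_triplets <- function(occ, path) {
  tr <- Matrix::summary(occ$O)
  df <- data.frame(bin_id = occ$bin_index[tr$i], cap = occ$caps[tr$j], value = 1L)
  df <- df[order(df$bin_id, df$cap), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
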