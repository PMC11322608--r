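# Small in-code fixtures shared across test files.

# A tiny two-chromosome binning (10 + 5 bins of 1 kb).
toy_binning <- function() {
  genome_binning(c(chrA = 10000, chrB = 5500), bin_width = 1000)
}

# GRanges helper from 0-based half-open triples.
gr0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

# An occupancy matrix built directly from a dense 0/1 matrix (bins x caps)
# on a single synthetic chromosome; bypasses peak I/O for unit tests.
toy_occupancy <- function(mat, bin_width = 1000) {
  caps <- colnames(mat)
  stopifnot(!is.null(caps))
  binning <- genome_binning(
    stats::setNames(nrow(mat) * bin_width, "chrT"), bin_width)
  structure(list(binning = binning, caps = caps,
                 O = Matrix::Matrix(mat, sparse = TRUE),
                 bin_index = seq_len(nrow(mat))),
            class = "OccupancyMatrix")
}

# Annotations from per-CAP flag vectors.
toy_annotations <- function(caps, llps = character(0), idr = character(0),
                            rbp = character(0), mlo = list(),
                            ppi = NULL) {
  df <- data.frame(cap = caps,
                   llps = as.integer(caps %in% llps),
                   idr = as.integer(caps %in% idr),
                   rbp = as.integer(caps %in% rbp),
                   mlo = vapply(caps, function(cp) {
                     ms <- names(mlo)[vapply(mlo, function(v) cp %in% v,
                                             logical(1))]
                     paste(ms, collapse = ",")
                   }, character(1)),
                   stringsAsFactors = FALSE)
  ppi_df <- if (is.null(ppi)) NULL else
    data.frame(cap_a = ppi[, 1], cap_b = ppi[, 2], stringsAsFactors = FALSE)
  suppressWarnings(read_cap_annotations(df, ppi_df, caps))
}

# Minimal hand-built CondSig for dedup / postprocess tests.
toy_condsig <- function(id, components, probs = NULL, mean_top3 = 0.7,
                        pos_bins = integer(0), context = "promoter") {
  if (is.null(probs)) probs <- rev(seq_along(components)) / 100
  structure(list(id = id, focus = components[[1]], context = context,
                 topic = 1L, components = components,
                 z_scores = stats::setNames(rep(2, length(components)),
                                            components),
                 phi_probs = stats::setNames(probs, components),
                 pos_bins = pos_bins, caps = components,
                 aurocs = c(F_LLPS = mean_top3), mean_top3 = mean_top3,
                 passing = "F_LLPS", is_condsig = TRUE),
            class = c("CondSig", "Signature"))
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Brute-force oracles, independent of the implementation paths they check.

oracle_f1 <- function(focus, other) {
  tp <- sum(focus & other); fp <- sum(!focus & other); fn <- sum(focus & !other)
  prec <- if (tp + fp == 0) NA else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA else tp / (tp + fn)
  if (is.na(prec) || is.na(rec) || prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

oracle_auroc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

oracle_ncpr_blocks <- function(seq, window = 10, thr = 0.5) {
  aa <- strsplit(seq, "")[[1]]
  ch <- ifelse(aa %in% c("R", "K", "H"), 1, ifelse(aa %in% c("D", "E"), -1, 0))
  L <- length(aa)
  if (L < window) return(data.frame(start = integer(0), end = integer(0),
                                    sign = character(0)))
  res <- list()
  for (sgn in c("+", "-")) {
    cover <- logical(L)
    for (s in 0:(L - window)) {
      ncpr <- sum(ch[(s + 1):(s + window)]) / window
      hit <- if (sgn == "+") ncpr > thr else ncpr < -thr
      if (hit) cover[(s + 1):(s + window)] <- TRUE
    }
    r <- rle(cover)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values))
      res[[length(res) + 1]] <- data.frame(start = starts[i] - 1,
                                           end = ends[i], sign = sgn)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(start = integer(0), end = integer(0),
                                      sign = character(0)))
  out[order(out$start, out$sign), , drop = FALSE]
}
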