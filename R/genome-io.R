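#' Genomic binning of a genome into fixed-width bins
#'
#' Partitions each chromosome into consecutive fixed-width bins
#' (0-based, half-open). Trailing partial bins at chromosome ends are
#' dropped so every bin has exactly `bin_width` bp, keeping per-bin
#' features comparable.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), in
#'   the desired chromosome order.
#' @param bin_width bin width in bp (default 1000).
#' @return A `GenomeBinning` object: list with `chrom_order`, `chrom_sizes`,
#'   `bin_width`, `n_bins` and `gr` (a [GenomicRanges::GRanges] of all bins
#'   in genomic order).
#' @examples
#' gb <- genome_binning(c(chr1 = 5000), bin_width = 1000)
#' length(gb$gr)  # 5 bins
#' @export
genome_binning <- function(chrom_sizes, bin_width = 1000) {
  stopifnot(length(chrom_sizes) >= 1, bin_width >= 1)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes < bin_width))
    warning("chromosome(s) shorter than bin_width contribute no bins")
  n_per <- floor(chrom_sizes / bin_width)
  if (sum(n_per) == 0) stop("no bins: all chromosomes shorter than bin_width")
  chroms <- rep(names(chrom_sizes), n_per)
  starts <- unlist(lapply(n_per, function(n)
    if (n > 0) seq.int(0, by = bin_width, length.out = n) else numeric(0)),
    use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    factor(chroms, levels = names(chrom_sizes)),
    IRanges::IRanges(start = starts + 1, width = bin_width))
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  structure(list(chrom_order = names(chrom_sizes),
                 chrom_sizes = chrom_sizes,
                 bin_width = bin_width,
                 n_bins = length(gr),
                 gr = gr),
            class = "GenomeBinning")
}

#' Read a chrom.sizes file
#'
#' @param path two-column whitespace-delimited file: chromosome name, length.
#' @return named numeric vector of lengths, order of appearance preserved.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty chrom.sizes file: ", path)
  out <- numeric(0)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 2) stop("malformed chrom.sizes line ", i, ": ", lines[[i]])
    len <- suppressWarnings(as.numeric(f[[2]]))
    if (is.na(len) || len <= 0 || len != floor(len))
      stop("malformed chrom.sizes line ", i, ": length must be a positive integer")
    if (f[[1]] %in% names(out)) stop("duplicate chromosome '", f[[1]], "' at line ", i)
    out[[f[[1]]]] <- len
  }
  out
}

#' Read a BED3+ peak file into a sorted GRanges
#'
#' Coordinates are BED convention: 0-based half-open. Intervals on
#' chromosomes absent from `chrom_sizes` are skipped with a warning;
#' `start >= end` is an error.
#'
#' @param path BED3+ file.
#' @param chrom_sizes optional named vector; when given, used to validate
#'   and order chromosomes.
#' @param cap_name optional CAP name stored in `metadata(gr)$cap_name`.
#' @return sorted [GenomicRanges::GRanges].
#' @export
read_bed <- function(path, chrom_sizes = NULL, cap_name = NULL) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "numeric", "numeric", rep(NA, 9))[1:max(3, count_bed_cols(path))],
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame(V1 = character(0), V2 = numeric(0), V3 = numeric(0))
      } else stop("failed to parse BED file ", path, ": ", conditionMessage(e))
    })
  bed_to_granges(df, chrom_sizes = chrom_sizes, cap_name = cap_name, src = path)
}

count_bed_cols <- function(path) {
  l1 <- readLines(path, n = 1)
  if (length(l1) == 0) return(3L)
  length(strsplit(l1, "\t", fixed = TRUE)[[1]])
}

# Shared constructor for BED-shaped data.frames (also used by the simulator).
bed_to_granges <- function(df, chrom_sizes = NULL, cap_name = NULL, src = "<data>") {
  if (nrow(df) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    if (ncol(df) < 3) stop("BED input ", src, " has fewer than 3 columns")
    chrom <- as.character(df[[1]]); start0 <- df[[2]]; end0 <- df[[3]]
    if (any(is.na(start0)) || any(is.na(end0)))
      stop("non-numeric coordinates in BED input ", src)
    bad <- which(start0 >= end0)
    if (length(bad) > 0)
      stop("BED input ", src, ": start >= end at record ", bad[[1]])
    if (any(start0 < 0)) stop("BED input ", src, ": negative start coordinate")
    if (!is.null(chrom_sizes)) {
      unknown <- !(chrom %in% names(chrom_sizes))
      if (any(unknown)) {
        warning("BED input ", src, ": skipping ", sum(unknown),
                " record(s) on unknown chromosome(s): ",
                paste(unique(chrom[unknown]), collapse = ", "))
        chrom <- chrom[!unknown]; start0 <- start0[!unknown]; end0 <- end0[!unknown]
      }
      over <- end0 > chrom_sizes[chrom]
      if (any(over)) stop("BED input ", src, ": interval beyond chromosome end")
    }
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start0 + 1, end = end0))
    if (!is.null(chrom_sizes)) {
      GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
      GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
    }
    gr <- GenomicRanges::sort(gr)
  }
  if (!is.null(cap_name)) S4Vectors::metadata(gr)$cap_name <- cap_name
  gr
}

#' Write a GRanges as BED3
#'
#' Inverse of [read_bed()] for interval content: 1-based closed GRanges
#' coordinates are emitted as 0-based half-open BED records in sorted order.
#'
#' @param gr a GRanges.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(format(df, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Promoter flags per bin from a gene annotation
#'
#' Promoters are strand-aware TSS +/- `flank` bp intervals, clipped to the
#' chromosome; a bin is promoter-flagged iff it overlaps at least one
#' promoter interval by >= 1 bp.
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (BED-style 0-based half-open gene bodies) or a BED6 file path.
#' @param binning a [genome_binning()] object.
#' @param flank promoter half-width in bp (default 3000).
#' @return logical vector, one flag per bin of `binning`.
#' @export
promoters_from_genes <- function(genes, binning, flank = 3000) {
  if (is.character(genes) && length(genes) == 1) {
    df <- utils::read.table(genes, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("gene annotation BED must have >= 6 columns (strand needed)")
    genes <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                        strand = df[[6]], stringsAsFactors = FALSE)
  }
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) stop("genes must have columns ", paste(req, collapse = ", "))
  if (any(!genes$strand %in% c("+", "-")))
    stop("missing or invalid strand in gene annotation; TSS is strand-dependent")
  # TSS in 0-based coordinates: start for '+', end-1 for '-'
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  p_start <- pmax(0, tss - flank)
  p_end <- pmin(unname(binning$chrom_sizes[genes$chrom]), tss + flank)
  ok <- p_end > p_start & genes$chrom %in% binning$chrom_order
  if (!all(ok)) warning("dropping ", sum(!ok), " gene(s) with empty/unknown promoter interval")
  prom <- GenomicRanges::GRanges(genes$chrom[ok],
                                 IRanges::IRanges(start = p_start[ok] + 1,
                                                  end = p_end[ok]))
  IRanges::overlapsAny(binning$gr, prom, minoverlap = 1L)
}

#' Read a bedGraph signal into per-bin values
#'
#' Per-bin value is the length-weighted mean of overlapping records;
#' uncovered portions of a bin contribute 0 (absent data convention).
#'
#' @param path 4-column bedGraph file (chrom, start, end, value).
#' @param binning a [genome_binning()] object.
#' @return numeric vector of per-bin signal values (>= 0), one per bin.
#' @export
read_signal_bedgraph <- function(path, binning) {
  df <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) {
                   if (grepl("no lines available", conditionMessage(e)))
                     data.frame(V1 = character(0), V2 = numeric(0),
                                V3 = numeric(0), V4 = numeric(0))
                   else stop("failed to parse bedGraph ", path, ": ",
                             conditionMessage(e))
                 })
  signal_from_records(df, binning, src = path)
}

signal_from_records <- function(df, binning, src = "<data>") {
  vals <- numeric(binning$n_bins)
  if (nrow(df) == 0) return(vals)
  if (ncol(df) < 4) stop("bedGraph ", src, " must have 4 columns")
  if (any(df[[4]] < 0)) stop("bedGraph ", src, ": negative signal values")
  keep <- df[[1]] %in% binning$chrom_order
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) return(vals)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(start = df[[2]] + 1, end = df[[3]]))
  hits <- GenomicRanges::findOverlaps(binning$gr, gr, minoverlap = 1L)
  if (length(hits) == 0) return(vals)
  ov <- IRanges::pintersect(binning$gr[S4Vectors::queryHits(hits)],
                            gr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  contrib <- w * df[[4]][S4Vectors::subjectHits(hits)]
  sums <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  vals[as.integer(names(sums))] <- unname(sums) / binning$bin_width
  vals
}

#' Read condensation-related CAP annotation tables
#'
#' Expects a TSV with header and columns `cap`, `llps`, `mlo`
#' (comma-separated MLO names or empty), `idr`, `rbp`, and optionally
#' `ps_self`, `ps_part`, `sequence`. A separate two-column TSV (`cap_a`,
#' `cap_b`) carries pairwise protein-protein interaction edges. CAPs in the
#' tables but not in `caps` are ignored with a warning; CAPs absent from the
#' tables get all-false/0 annotations with a warning.
#'
#' @param path annotation TSV path (or a data.frame).
#' @param ppi_path optional PPI edge TSV path (or a 2-column data.frame).
#' @param caps character vector of CAP names the annotations should cover.
#' @return a `CapAnnotations` object (list of named per-CAP vectors plus a
#'   symmetric PPI edge set).
#' @export
read_cap_annotations <- function(path, ppi_path = NULL, caps) {
  df <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      quote = "", comment.char = "")
  if (!"cap" %in% names(df)) stop("annotation table needs a 'cap' column")
  unknown <- setdiff(df$cap, caps)
  if (length(unknown) > 0) {
    warning("ignoring ", length(unknown), " annotation row(s) for unknown CAP(s): ",
            paste(utils::head(unknown, 5), collapse = ", "))
    df <- df[df$cap %in% caps, , drop = FALSE]
  }
  missing <- setdiff(caps, df$cap)
  if (length(missing) > 0)
    warning(length(missing), " CAP(s) missing from annotation table; ",
            "assigned all-false/0 annotations")
  grab_flag <- function(col) {
    v <- stats::setNames(rep(FALSE, length(caps)), caps)
    if (col %in% names(df)) v[df$cap] <- as.logical(as.integer(df[[col]]) != 0)
    v
  }
  grab_score <- function(col) {
    if (!col %in% names(df)) return(NULL)
    v <- stats::setNames(rep(0, length(caps)), caps)
    v[df$cap] <- as.numeric(df[[col]])
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop(col, " scores must lie in [0,1]")
    v
  }
  mlo <- stats::setNames(vector("list", length(caps)), caps)
  mlo[] <- list(character(0))
  if ("mlo" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      m <- df$mlo[[i]]
      if (!is.na(m) && nzchar(m))
        mlo[[df$cap[[i]]]] <- strsplit(m, ",", fixed = TRUE)[[1]]
    }
  }
  seqs <- NULL
  if ("sequence" %in% names(df)) {
    seqs <- stats::setNames(rep(NA_character_, length(caps)), caps)
    seqs[df$cap] <- df$sequence
  }
  ppi <- matrix(character(0), ncol = 2)
  if (!is.null(ppi_path)) {
    pdf <- if (is.data.frame(ppi_path)) ppi_path else
      utils::read.table(ppi_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, quote = "", comment.char = "")
    if (ncol(pdf) < 2) stop("PPI table needs two columns")
    keep <- pdf[[1]] %in% caps & pdf[[2]] %in% caps
    if (any(!keep))
      warning("ignoring ", sum(!keep), " PPI edge(s) touching unknown CAP(s)")
    pdf <- pdf[keep, , drop = FALSE]
    if (nrow(pdf) > 0) {
      a <- pmin(pdf[[1]], pdf[[2]]); b <- pmax(pdf[[1]], pdf[[2]])
      ppi <- unique(cbind(a, b))
    }
  }
  structure(list(caps = caps,
                 is_llps = grab_flag("llps"),
                 has_idr = grab_flag("idr"),
                 is_rbp = grab_flag("rbp"),
                 mlo_memberships = mlo,
                 ps_self = grab_score("ps_self"),
                 ps_part = grab_score("ps_part"),
                 sequence = seqs,
                 ppi_edges = ppi),
            class = "CapAnnotations")
}

# Canonical key for an unordered CAP pair.
ppi_pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

has_ppi_edge <- function(annotations, a, b) {
  if (nrow(annotations$ppi_edges) == 0) return(logical(length(a)))
  keys <- ppi_pair_key(annotations$ppi_edges[, 1], annotations$ppi_edges[, 2])
  ppi_pair_key(a, b) %in% keys
}

#' Permute CAP annotations across CAPs
#'
#' Applies one random permutation of CAP identities to every annotation
#' column (LLPS/IDR/RBP flags, MLO memberships, PS scores) and relabels PPI
#' edge endpoints with the same permutation, preserving all marginal counts.
#' Used as the annotation-shuffle null for signature filtration.
#'
#' @param annotations a `CapAnnotations` object.
#' @param seed integer seed for the permutation.
#' @return a permuted `CapAnnotations` object.
#' @export
shuffle_annotations <- function(annotations, seed) {
  caps <- annotations$caps
  set.seed(seed)
  perm <- sample(caps)                       # perm[i] receives caps[i]'s annotations
  map <- stats::setNames(perm, caps)         # old name -> new carrier
  out <- annotations
  rename <- function(v) stats::setNames(v, unname(map[names(v)]))[caps]
  out$is_llps <- rename(annotations$is_llps)
  out$has_idr <- rename(annotations$has_idr)
  out$is_rbp <- rename(annotations$is_rbp)
  out$mlo_memberships <- stats::setNames(annotations$mlo_memberships,
                                         unname(map[names(annotations$mlo_memberships)]))[caps]
  if (!is.null(annotations$ps_self)) out$ps_self <- rename(annotations$ps_self)
  if (!is.null(annotations$ps_part)) out$ps_part <- rename(annotations$ps_part)
  if (!is.null(annotations$sequence)) out$sequence <- rename(annotations$sequence)
  if (nrow(annotations$ppi_edges) > 0) {
    a <- unname(map[annotations$ppi_edges[, 1]])
    b <- unname(map[annotations$ppi_edges[, 2]])
    out$ppi_edges <- unique(cbind(pmin(a, b), pmax(a, b)))
  }
  out
}
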