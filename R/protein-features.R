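#' Charged amino-acid blocks by sliding-window net charge per residue
#'
#' Computes NCPR over a 10-residue sliding window with step 1:
#' `(count(R, K, H) - count(D, E)) / 10`, counting histidine as positive.
#' Windows with NCPR > 0.5 (positive blocks) or < -0.5 (negative blocks)
#' are charged blocks; overlapping windows of the same sign are merged
#' (blocks of opposite sign may overlap). Also returns the fraction of
#' residues covered by any block, a multivalency proxy.
#'
#' @param sequence amino-acid string over the 20 standard residues;
#'   non-standard letters count as neutral.
#' @param window window size in residues (default 10).
#' @param threshold absolute NCPR threshold, strict (default 0.5).
#' @return list with `blocks` (data.frame: `start`, `end` 0-based
#'   half-open residue coordinates, `sign`, `max_ncpr`) and
#'   `charged_fraction`. Sequences shorter than `window` give zero blocks.
#' @export
charged_blocks <- function(sequence, window = 10, threshold = 0.5) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  empty <- list(blocks = data.frame(start = integer(0), end = integer(0),
                                    sign = character(0), max_ncpr = numeric(0)),
                charged_fraction = 0)
  if (L < window) return(empty)
  charge <- ifelse(aa %in% c("R", "K", "H"), 1, ifelse(aa %in% c("D", "E"), -1, 0))
  # NCPR of window starting at 0-based position s covers residues [s, s+window)
  cs <- cumsum(c(0, charge))
  starts0 <- 0:(L - window)
  ncpr <- (cs[starts0 + window + 1] - cs[starts0 + 1]) / window
  merge_sign <- function(sel, sign) {
    if (!any(sel)) return(NULL)
    s <- starts0[sel]
    runs <- split(s, cumsum(c(1, diff(s) >= window)))  # non-overlapping -> new block
    do.call(rbind, lapply(runs, function(r) {
      # consecutive/overlapping same-sign windows merge into one block
      data.frame(start = as.integer(min(r)), end = as.integer(max(r) + window),
                 sign = sign,
                 max_ncpr = if (sign == "+") max(ncpr[sel][s %in% r])
                            else min(ncpr[sel][s %in% r]))
    }))
  }
  blocks <- rbind(merge_sign(ncpr > threshold, "+"),
                  merge_sign(ncpr < -threshold, "-"))
  if (is.null(blocks)) return(empty)
  blocks <- blocks[order(blocks$start, blocks$sign), , drop = FALSE]
  rownames(blocks) <- NULL
  covered <- logical(L)
  for (i in seq_len(nrow(blocks)))
    covered[(blocks$start[i] + 1):blocks$end[i]] <- TRUE
  list(blocks = blocks, charged_fraction = mean(covered))
}

#' Charged-block annotation for a set of protein sequences
#'
#' @param sequences named character vector of amino-acid sequences.
#' @return data.frame with one row per protein: `protein`, `n_blocks`,
#'   `charged_fraction`.
#' @export
annotate_charged_blocks <- function(sequences) {
  stopifnot(!is.null(names(sequences)))
  rows <- lapply(names(sequences), function(p) {
    cb <- charged_blocks(sequences[[p]])
    data.frame(protein = p, n_blocks = nrow(cb$blocks),
               charged_fraction = cb$charged_fraction)
  })
  do.call(rbind, rows)
}

# Initial centroids fixed by the clustering design: PS-Self x PS-Part.
ps_centroids <- function() {
  matrix(c(0.8, 0.8,
           0.8, 0.4,
           0.4, 0.8,
           0.4, 0.4),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("Both", "Self", "Part", "None"),
                         c("ps_self", "ps_part")))
}

#' Four-way k-means labelling of phase-separation scores
#'
#' Clusters CAPs on their (PS-Self, PS-Part) scores with k = 4 and fixed
#' initial centroids (0.8, 0.8), (0.8, 0.4), (0.4, 0.8), (0.4, 0.4),
#' labelled Both / Self / Part / None by initial-centroid identity. Lloyd
#' iterations run to an assignment fixpoint (max 300); a cluster that
#' empties is reseeded to its initial centroid. With fewer than 4 points,
#' each point is assigned to its nearest initial centroid without
#' iteration.
#'
#' @param ps_scores data.frame or matrix with columns `ps_self` and
#'   `ps_part`, values in \[0, 1\]; row names identify CAPs.
#' @return data.frame with `ps_self`, `ps_part` and factor `cluster`
#'   (levels Both, Self, Part, None).
#' @export
ps_kmeans <- function(ps_scores) {
  x <- as.matrix(ps_scores[, c("ps_self", "ps_part")])
  if (any(x < 0 | x > 1)) stop("PS scores must lie in [0,1]")
  init <- ps_centroids()
  labels <- rownames(init)
  assign_nearest <- function(cent) {
    d2 <- outer(rowSums(x^2), rowSums(cent^2), "+") - 2 * x %*% t(cent)
    max.col(-d2, ties.method = "first")
  }
  if (nrow(x) < 4) {
    cl <- assign_nearest(init)
  } else {
    cent <- init
    cl <- assign_nearest(cent)
    for (it in seq_len(300)) {
      for (g in 1:4) {
        cent[g, ] <- if (any(cl == g)) colMeans(x[cl == g, , drop = FALSE])
                     else init[g, ]  # empty cluster: reseed to initial centroid
      }
      cl_new <- assign_nearest(cent)
      if (all(cl_new == cl)) break
      cl <- cl_new
    }
  }
  data.frame(ps_self = x[, 1], ps_part = x[, 2],
             cluster = factor(labels[cl], levels = labels),
             row.names = rownames(ps_scores))
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}
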