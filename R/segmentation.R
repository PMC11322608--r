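#' Co-occupancy F1 score between a focus CAP and another CAP
#'
#' Treats the other CAP's occupancy vector as a classifier of the focus
#' CAP's occupancy (positive class = occupied) and returns the F1 score,
#' the harmonic mean of precision and recall. Returns 0 when
#' precision + recall is 0 (disjoint supports).
#'
#' @param focus_col binary occupancy vector of the focus CAP.
#' @param other_col binary occupancy vector of the candidate CAP.
#' @return F1 score in \[0, 1\].
#' @export
co_occupancy_f1 <- function(focus_col, other_col) {
  if (length(focus_col) != length(other_col))
    stop("occupancy vectors must have equal length")
  if (!is_binary(focus_col) || !is_binary(other_col))
    stop("occupancy vectors must be binary (0/1)")
  tp <- sum(focus_col == 1 & other_col == 1)
  fp <- sum(focus_col == 0 & other_col == 1)
  fn <- sum(focus_col == 1 & other_col == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Build the focus-CAP segment of the occupancy matrix
#'
#' For a focus CAP, scores every other retained CAP by co-occupancy F1
#' (beta), keeps the top `q` (ties at the cut broken by CAP name), z-scores
#' the kept betas (population sd) to gamma, computes the per-bin occupancy
#' score `delta_i = sum_j gamma_j O[i, j]` over the kept members, and
#' retains bins with `delta > 0`. The focus CAP itself is excluded from the
#' beta ranking but appended to the member set so it can appear as a word
#' in downstream documents.
#'
#' @param occ a filtered `OccupancyMatrix`.
#' @param focus_cap name of the focus CAP.
#' @param q member-count cap (default 50).
#' @return a `Segment` (list with `focus`, `members`, `beta`, `gamma`,
#'   `caps` = members + focus, `bins` (row indices into `occ`), `delta`,
#'   `context`), or `NULL` with a message when no bin has positive delta
#'   (degenerate segment, skipped).
#' @export
build_segment <- function(occ, focus_cap, q = 50) {
  stopifnot(inherits(occ, "OccupancyMatrix"))
  if (!focus_cap %in% occ$caps) stop("focus CAP '", focus_cap, "' not in matrix")
  candidates <- setdiff(occ$caps, focus_cap)
  if (length(candidates) < 2) stop("fewer than 2 candidate CAPs")
  focus_col <- as.numeric(occ$O[, focus_cap])
  beta <- vapply(candidates, function(cj)
    co_occupancy_f1(focus_col, as.numeric(occ$O[, cj])), numeric(1))
  ord <- order(-beta, candidates)
  members <- candidates[ord][seq_len(min(q, length(candidates)))]
  beta_kept <- beta[members]
  gamma <- pop_zscore(beta_kept)
  names(gamma) <- members
  delta <- as.numeric(occ$O[, members, drop = FALSE] %*% gamma)
  keep <- which(delta > 0)
  if (length(keep) == 0) {
    message("segment for focus CAP '", focus_cap,
            "' has no bin with positive occupancy score; skipped")
    return(NULL)
  }
  structure(list(focus = focus_cap,
                 members = members,
                 beta = beta_kept,
                 gamma = gamma,
                 caps = c(members, focus_cap),
                 bins = keep,
                 delta = delta[keep],
                 context = "unsplit"),
            class = "Segment")
}

#' Split a segment into promoter and non-promoter contexts
#'
#' Partitions the segment's bins by the promoter flag; member CAPs, beta
#' and gamma are unchanged. Empty contexts are dropped with a message.
#'
#' @param segment a `Segment`.
#' @param promoter_map logical vector over the occupancy rows the segment
#'   indexes into (`TRUE` = promoter bin).
#' @return named list with up to two entries, `promoter` and
#'   `non-promoter`.
#' @export
split_context <- function(segment, promoter_map) {
  stopifnot(inherits(segment, "Segment"))
  if (max(segment$bins) > length(promoter_map))
    stop("promoter_map does not cover segment bins")
  out <- list()
  for (ctx in c("promoter", "non-promoter")) {
    sel <- if (ctx == "promoter") promoter_map[segment$bins]
           else !promoter_map[segment$bins]
    if (!any(sel)) {
      message("segment for '", segment$focus, "': empty ", ctx,
              " context dropped")
      next
    }
    sub <- segment
    sub$bins <- segment$bins[sel]
    sub$delta <- segment$delta[sel]
    sub$context <- ctx
    out[[ctx]] <- sub
  }
  out
}

#' Dump a segment's member table for inspection
#'
#' @param segment a `Segment`.
#' @param path output TSV path.
#' @export
write_segment_tsv <- function(segment, path) {
  df <- data.frame(cap = segment$members,
                   beta = unname(segment$beta),
                   gamma = unname(segment$gamma))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
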