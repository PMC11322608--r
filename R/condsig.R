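#' Call co-occupancy signatures from a fitted topic model
#'
#' For each topic, component CAPs are the words whose z-scored occurrence
#' probability (population z over the topic's row of the word distribution)
#' exceeds `lambda_z`. Signature-positive bins are the segment bins
#' occupied by more than `pos_frac` of the components, implemented as
#' count >= `ceiling(pos_frac * n_components)`. Topics yielding fewer than
#' `min_components` components or fewer than `min_positive` positive bins
#' are dropped.
#'
#' @param model a `TopicModel`.
#' @param corpus the `Corpus` it was fitted to.
#' @param segment the `Segment` the corpus came from.
#' @param lambda_z z-score threshold for components (default 1.3).
#' @param pos_frac fraction of components required at positive bins
#'   (default 0.8).
#' @param min_components minimum component count (default 3).
#' @param min_positive minimum positive-bin count (default 200).
#' @param occ the `OccupancyMatrix` (for member occupancy at segment bins).
#' @return list of `Signature` objects (possibly empty). Each has `id`,
#'   `focus`, `context`, `topic`, `components`, `z_scores`, `phi_probs`,
#'   `pos_bins` (occupancy row indices) and `caps` (the segment vocabulary).
#' @export
call_signatures <- function(model, corpus, segment, occ, lambda_z = 1.3,
                            pos_frac = 0.8, min_components = 3,
                            min_positive = 200) {
  out <- list()
  sub <- occ$O[segment$bins, corpus$vocab, drop = FALSE]
  for (t in seq_len(model$k)) {
    z <- pop_zscore(model$phi[t, ])
    comp <- corpus$vocab[z > lambda_z]
    if (length(comp) < min_components) next
    h <- ceiling(pos_frac * length(comp))
    n_occ <- Matrix::rowSums(sub[, comp, drop = FALSE])
    pos <- segment$bins[n_occ >= h]
    if (length(pos) < min_positive) next
    out[[length(out) + 1]] <- structure(
      list(id = paste(segment$focus, segment$context, t, sep = ":"),
           focus = segment$focus, context = segment$context, topic = t,
           components = comp,
           z_scores = stats::setNames(z[match(comp, corpus$vocab)], comp),
           phi_probs = stats::setNames(model$phi[t, ], corpus$vocab),
           pos_bins = pos, caps = corpus$vocab),
      class = "Signature")
  }
  out
}

#' Define signature-negative bins
#'
#' Negative bins are the context-matched, post-filter bins genome-wide
#' that are comparably occupied — at least `h = ceiling(pos_frac *
#' n_components)` occupied members of the segment's CAPs — yet lack
#' component co-occupancy (fewer than 2 occupied components). Positive
#' bins are excluded.
#'
#' @param signature a `Signature`.
#' @param occ the filtered `OccupancyMatrix`.
#' @param context_bins integer vector of occupancy row indices in the
#'   signature's context (e.g. all promoter bins).
#' @param pos_frac fraction used for the comparability threshold
#'   (default 0.8, matching the positive-bin rule).
#' @return integer vector of negative-bin row indices (possibly empty).
#' @export
define_negative_bins <- function(signature, occ, context_bins, pos_frac = 0.8) {
  h <- ceiling(pos_frac * length(signature$components))
  sub_all <- occ$O[context_bins, signature$caps, drop = FALSE]
  n_members <- Matrix::rowSums(sub_all)
  n_comp <- Matrix::rowSums(sub_all[, signature$components, drop = FALSE])
  neg <- context_bins[n_members >= h & n_comp < 2]
  setdiff(neg, signature$pos_bins)
}

#' Compute per-bin condensation-related features
#'
#' For each bin, over the CAPs of the signature's segment that occupy it:
#' `F_LLPS`, `F_IDR`, `F_RBP` are the fractions of occupied CAPs with the
#' corresponding annotation; `F_MLO` is the best single membrane-less
#' organelle's member fraction (max over MLOs); `F_PPI` is the fraction of
#' occupied CAP pairs with a protein-protein interaction edge (0 when
#' fewer than 2 CAPs are occupied); `S_RBS` is the RNA-binding-strength
#' signal at the bin when a track is supplied. Bins with zero occupied
#' CAPs are excluded (all-NA row).
#'
#' @param bins integer vector of occupancy row indices.
#' @param occ the `OccupancyMatrix`.
#' @param caps CAPs of the segment to count occupancy over.
#' @param annotations a `CapAnnotations` object.
#' @param rbs optional numeric per-bin signal over all bins of the binning
#'   (indexed via `occ$bin_index`).
#' @return data.frame with one row per bin and columns `F_LLPS`, `F_MLO`,
#'   `F_IDR`, `F_PPI`, `F_RBP` and (when `rbs` is given) `S_RBS`, plus
#'   `n_occupied`.
#' @export
compute_features <- function(bins, occ, caps, annotations, rbs = NULL) {
  sub <- as.matrix(occ$O[bins, caps, drop = FALSE])
  n <- length(bins)
  no <- rowSums(sub)
  occupied <- no > 0
  frac_of <- function(flag) {
    v <- as.numeric(sub %*% as.numeric(flag[caps])) / no
    v[!occupied] <- NA_real_
    v
  }
  f <- data.frame(F_LLPS = frac_of(annotations$is_llps),
                  F_MLO = NA_real_,
                  F_IDR = frac_of(annotations$has_idr),
                  F_PPI = NA_real_,
                  F_RBP = frac_of(annotations$is_rbp))
  # F_MLO: best single MLO's member fraction among occupied CAPs
  mlo_names <- unique(unlist(annotations$mlo_memberships[caps]))
  if (length(mlo_names) == 0) {
    f$F_MLO <- ifelse(occupied, 0, NA_real_)
  } else {
    mlo_mat <- vapply(mlo_names, function(m)
      vapply(caps, function(cp)
        as.numeric(m %in% annotations$mlo_memberships[[cp]]), numeric(1)),
      numeric(length(caps)))
    counts <- sub %*% mlo_mat              # bins x MLOs
    f$F_MLO <- apply(counts, 1, max) / no
    f$F_MLO[!occupied] <- NA_real_
  }
  # F_PPI: occupied pairs with an edge / all occupied pairs, via the
  # adjacency quadratic form x'Ax = 2 * (edges among occupied)
  adj <- matrix(0, length(caps), length(caps),
                dimnames = list(caps, caps))
  if (nrow(annotations$ppi_edges) > 0) {
    e <- annotations$ppi_edges
    e <- e[e[, 1] %in% caps & e[, 2] %in% caps, , drop = FALSE]
    if (nrow(e) > 0) {
      adj[cbind(e[, 1], e[, 2])] <- 1
      adj[cbind(e[, 2], e[, 1])] <- 1
    }
  }
  edge_counts <- rowSums((sub %*% adj) * sub) / 2
  n_pairs <- no * (no - 1) / 2
  f$F_PPI <- ifelse(n_pairs > 0, edge_counts / n_pairs, 0)
  f$F_PPI[!occupied] <- NA_real_
  f$n_occupied <- as.integer(no)
  if (!is.null(rbs)) f$S_RBS <- rbs[occ$bin_index[bins]]
  f
}

#' Rank-based AUROC with midranks
#'
#' Mann-Whitney AUROC: equals `P(pos > neg) + 0.5 P(pos == neg)` over all
#' positive/negative value pairs, computed from midranks.
#'
#' @param positive_values numeric vector of feature values at positive bins.
#' @param negative_values numeric vector at negative bins.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(positive_values, negative_values) {
  np <- length(positive_values); nn <- length(negative_values)
  if (np == 0 || nn == 0) stop("both value sets must be non-empty")
  r <- rank(c(positive_values, negative_values), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Filter signatures to CondSigs by condensation-feature enrichment
#'
#' For each signature, computes one AUROC per available feature between
#' positive- and negative-bin feature values. A signature passes iff at
#' least `min_passing` features have AUROC strictly above `auroc_min` and
#' the mean of the top three AUROCs is strictly above `mean_top3_min`.
#' Signatures with no negative bins are scored as non-CondSigs with a
#' warning.
#'
#' @param signatures list of `Signature` objects.
#' @param occ the filtered `OccupancyMatrix`.
#' @param annotations a `CapAnnotations` object.
#' @param promoter_map logical promoter flag per occupancy row.
#' @param rbs optional per-bin RNA-binding-strength signal (all bins of
#'   the binning).
#' @param auroc_min per-feature AUROC threshold (default 0.6).
#' @param mean_top3_min top-three mean AUROC threshold (default 0.65).
#' @param min_passing minimum count of passing features (default 3).
#' @param pos_frac comparability fraction for negative bins (default 0.8).
#' @return list of `CondSig` objects (signature plus `aurocs`,
#'   `mean_top3`, `passing`, `is_condsig`), one per input signature.
#' @export
score_signatures <- function(signatures, occ, annotations, promoter_map,
                             rbs = NULL, auroc_min = 0.6,
                             mean_top3_min = 0.65, min_passing = 3,
                             pos_frac = 0.8) {
  all_rows <- seq_len(nrow(occ$O))
  ctx_bins <- list("promoter" = all_rows[promoter_map],
                   "non-promoter" = all_rows[!promoter_map],
                   "unsplit" = all_rows)
  lapply(signatures, function(sig) {
    neg <- define_negative_bins(sig, occ, ctx_bins[[sig$context]],
                                pos_frac = pos_frac)
    cs <- sig
    class(cs) <- c("CondSig", "Signature")
    cs$neg_bins <- neg
    if (length(neg) == 0) {
      warning("signature ", sig$id, " has no negative bins; scored as non-CondSig")
      cs$aurocs <- stats::setNames(numeric(0), character(0))
      cs$mean_top3 <- NA_real_
      cs$passing <- character(0)
      cs$is_condsig <- FALSE
      return(cs)
    }
    fp <- compute_features(sig$pos_bins, occ, sig$caps, annotations, rbs)
    fn <- compute_features(neg, occ, sig$caps, annotations, rbs)
    feats <- c("F_LLPS", "F_MLO", "F_IDR", "F_PPI", "F_RBP",
               if (!is.null(rbs)) "S_RBS")
    aur <- vapply(feats, function(ft) {
      pv <- fp[[ft]][!is.na(fp[[ft]])]
      nv <- fn[[ft]][!is.na(fn[[ft]])]
      auroc(pv, nv)
    }, numeric(1))
    cs$aurocs <- aur
    cs$mean_top3 <- mean(sort(aur, decreasing = TRUE)[seq_len(min(3, length(aur)))])
    cs$passing <- names(aur)[aur > auroc_min]
    cs$is_condsig <- length(cs$passing) >= min_passing &&
      cs$mean_top3 > mean_top3_min
    cs
  })
}

# Top components of a CondSig ranked by occurrence probability.
top_components <- function(condsig, n = 5) {
  pr <- condsig$phi_probs[condsig$components]
  condsig$components[order(-pr, condsig$components)][seq_len(min(n, length(pr)))]
}

#' Remove redundant CondSigs
#'
#' CondSigs (pooled within a cell type, across contexts) are compared by
#' the Jaccard index of their top five components ranked by occurrence
#' probability. Greedy selection: sort by mean top-three AUROC descending
#' and keep a CondSig iff its top-5 Jaccard with every already-kept
#' CondSig is <= `dedup_jaccard`; of a redundant pair the lower-scoring
#' one is discarded.
#'
#' @param condsigs list of passing `CondSig` objects.
#' @param dedup_jaccard redundancy threshold (default 0.25).
#' @param per_context if `TRUE`, deduplicate within each context
#'   separately instead of pooling (default `FALSE`).
#' @return deduplicated list of `CondSig` objects; pairwise top-5 Jaccard
#'   of the output is <= `dedup_jaccard`.
#' @export
deduplicate <- function(condsigs, dedup_jaccard = 0.25, per_context = FALSE) {
  if (length(condsigs) <= 1) return(condsigs)
  if (per_context) {
    ctxs <- vapply(condsigs, `[[`, character(1), "context")
    return(unlist(lapply(unique(ctxs), function(cx)
      deduplicate(condsigs[ctxs == cx], dedup_jaccard, FALSE)),
      recursive = FALSE))
  }
  scores <- vapply(condsigs, `[[`, numeric(1), "mean_top3")
  ids <- vapply(condsigs, `[[`, character(1), "id")
  ord <- order(-scores, ids)
  tops <- lapply(condsigs, top_components)
  kept <- integer(0)
  for (i in ord) {
    if (all(vapply(kept, function(j) jaccard(tops[[i]], tops[[j]]),
                   numeric(1)) <= dedup_jaccard))
      kept <- c(kept, i)
  }
  condsigs[sort(kept)]
}

#' Merge positive bins of final CondSigs into genomic sites
#'
#' Union of positive bins over the given CondSigs, with book-ended and
#' overlapping bins merged into maximal intervals.
#'
#' @param condsigs list of `CondSig` objects.
#' @param occ the `OccupancyMatrix` defining the bin coordinates.
#' @return GRanges of merged CondSig-positive sites.
#' @export
positive_sites <- function(condsigs, occ) {
  rows <- sort(unique(unlist(lapply(condsigs, `[[`, "pos_bins"))))
  if (length(rows) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(occ$binning$gr[occ$bin_index[rows]])
}
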