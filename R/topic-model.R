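#' Build a biterm corpus from a segment
#'
#' Each segment bin becomes one document whose words are the member CAPs
#' (including the focus CAP) occupying that bin; each document contributes
#' all unordered word pairs (biterms), with repeats across documents
#' retained (frequency matters). Documents with fewer than two words
#' contribute no biterms.
#'
#' @param segment a `Segment`.
#' @param occ the `OccupancyMatrix` the segment was built from.
#' @return a `Corpus`: list with `vocab` (member CAPs), `docs` (list of
#'   integer word-id vectors), `biterms` (N x 2 integer matrix of word
#'   ids), `doc_of` (document index of each biterm) and `bins` (occupancy
#'   row index per document).
#' @export
corpus_from_segment <- function(segment, occ) {
  stopifnot(inherits(segment, "Segment"), inherits(occ, "OccupancyMatrix"))
  vocab <- segment$caps
  sub <- as.matrix(occ$O[segment$bins, vocab, drop = FALSE])
  docs <- lapply(seq_len(nrow(sub)), function(i) which(sub[i, ] != 0))
  # pair-index templates cached per document length
  templates <- list()
  pair_template <- function(L) {
    key <- as.character(L)
    if (is.null(templates[[key]]))
      templates[[key]] <<- t(utils::combn(L, 2))
    templates[[key]]
  }
  bt <- list(); dof <- list()
  for (d in seq_along(docs)) {
    w <- docs[[d]]
    if (length(w) >= 2) {
      tpl <- pair_template(length(w))
      bt[[length(bt) + 1]] <- cbind(w[tpl[, 1]], w[tpl[, 2]])
      dof[[length(dof) + 1]] <- rep(d, nrow(tpl))
    }
  }
  biterms <- if (length(bt) > 0) do.call(rbind, bt) else
    matrix(integer(0), ncol = 2)
  structure(list(vocab = vocab, docs = docs, biterms = biterms,
                 doc_of = unlist(dof) %||% integer(0),
                 bins = segment$bins),
            class = "Corpus")
}

#' Fit a biterm topic model by collapsed Gibbs sampling
#'
#' Runs `n_iter` full sweeps of collapsed Gibbs over the biterm topic
#' assignments and takes a point estimate from the final counts (no
#' burn-in averaging). Per-document topic distributions are inferred as
#' `theta_doc[d, t] = sum_b P(t | b) P(b | d)` with
#' `P(t | b) proportional to theta_global[t] phi[t, w1] phi[t, w2]` and
#' `P(b | d)` the biterm frequency within the document; documents with no
#' biterms receive the global topic distribution. A fixed `seed` makes the
#' fit bit-identical.
#'
#' @param corpus a `Corpus`.
#' @param k topic count (>= 1).
#' @param alpha_topic Dirichlet prior on topics; default `50 / k`.
#' @param beta_word Dirichlet prior on words; default 0.01.
#' @param n_iter Gibbs sweeps; default 500.
#' @param seed integer seed.
#' @return a `TopicModel`: list with `k`, `phi` (k x V, rows sum to 1),
#'   `theta_doc` (p x k, rows sum to 1), `theta_global`, hyperparameters
#'   and `seed`.
#' @export
fit_btm <- function(corpus, k, alpha_topic = 50 / k, beta_word = 0.01,
                    n_iter = 500, seed = 1) {
  stopifnot(inherits(corpus, "Corpus"), k >= 1)
  if (nrow(corpus$biterms) == 0) stop("corpus too sparse: no biterms")
  V <- length(corpus$vocab)
  set.seed(seed)
  fit <- btm_gibbs(corpus$biterms, V, as.integer(k),
                   alpha_topic, beta_word, as.integer(n_iter))
  phi <- fit$phi
  colnames(phi) <- corpus$vocab
  theta_global <- as.numeric(fit$theta_global)
  # P(t | b) for every biterm instance
  ptb <- t(theta_global * phi[, corpus$biterms[, 1], drop = FALSE] *
             phi[, corpus$biterms[, 2], drop = FALSE])  # N x k
  ptb <- ptb / rowSums(ptb)
  p <- length(corpus$docs)
  theta_doc <- matrix(rep(theta_global, each = p), nrow = p)
  has_bt <- sort(unique(corpus$doc_of))
  agg <- rowsum(ptb, group = corpus$doc_of)
  counts <- as.numeric(table(corpus$doc_of))
  theta_doc[has_bt, ] <- agg / counts
  structure(list(k = k, phi = phi, theta_doc = theta_doc,
                 theta_global = theta_global,
                 alpha_topic = alpha_topic, beta_word = beta_word,
                 n_iter = n_iter, seed = seed),
            class = "TopicModel")
}

#' Specificity score of a topic fit
#'
#' `SS_k = log((1/k) sum_j sigma_j / mu_j^2)` over the columns of the
#' document-topic matrix, where `sigma_j` and `mu_j` are the population
#' variance and mean of column j. An epsilon floor (1e-12) inside the log
#' guards degenerate (uniform) fits. Higher is better: topics should occur
#' with very different probabilities across documents.
#'
#' @param theta_doc p x k document-topic matrix.
#' @param eps floor inside the log (default 1e-12).
#' @return SS_k (scalar).
#' @export
specificity_score <- function(theta_doc, eps = 1e-12) {
  mu <- colMeans(theta_doc)
  sig <- colMeans(sweep(theta_doc, 2, mu)^2)
  log(max(mean(sig / mu^2), eps))
}

#' Purity score of a topic fit
#'
#' `PS_k = log((1/p) sum_i sigma_i)` over the rows of the document-topic
#' matrix, where `sigma_i` is the population variance of row i. An epsilon
#' floor inside the log guards uniform rows. Higher is better: each
#' document should be dominated by few topics.
#'
#' @inheritParams specificity_score
#' @return PS_k (scalar).
#' @export
purity_score <- function(theta_doc, eps = 1e-12) {
  sig <- rowMeans((theta_doc - rowMeans(theta_doc))^2)
  log(max(mean(sig), eps))
}

#' Combination score for topic-number selection
#'
#' `CS_k = alpha SS_k + (1 - alpha) PS_k` with
#' `alpha = PS_k / (SS_k + PS_k)`; when `SS_k + PS_k == 0`, `alpha` is
#' defined as 0.5.
#'
#' @param ss specificity score.
#' @param ps purity score.
#' @return list with `alpha` and `cs`.
#' @export
combination_score <- function(ss, ps) {
  alpha <- if (ss + ps == 0) 0.5 else ps / (ss + ps)
  list(alpha = alpha, cs = alpha * ss + (1 - alpha) * ps)
}

#' Fit models over a range of topic numbers and select the best
#'
#' Fits one seeded model per k (optionally `reps` fits, keeping the
#' highest-CS one per k), scores each with the combination score and
#' returns the model with maximal `CS_k` (ties broken toward smaller k).
#'
#' @param corpus a `Corpus`.
#' @param k_range integer vector of topic numbers (default 2:10).
#' @param seed integer base seed; per-k sampler seeds are derived from it.
#' @param reps fits per k (default 1).
#' @param alpha_topic,beta_word,n_iter passed to [fit_btm()];
#'   `alpha_topic = NULL` means the 50/k default.
#' @param seed_fn optional function(k, rep) -> integer seed, overriding the
#'   default derivation (used by the pipeline to fan out a global seed).
#' @return list with `model` (best `TopicModel`) and `report` (data.frame
#'   with one row per evaluated k: k, ss, ps, alpha, cs, chosen).
#' @export
select_topic_number <- function(corpus, k_range = 2:10, seed = 1, reps = 1,
                                alpha_topic = NULL, beta_word = 0.01,
                                n_iter = 500, seed_fn = NULL) {
  stopifnot(length(k_range) >= 1)
  if (is.null(seed_fn))
    seed_fn <- function(k, rep) (seed + 7919L * k + 104729L * (rep - 1L)) %% 2147483647L
  rows <- list(); models <- list()
  for (k in k_range) {
    best_k <- NULL
    for (r in seq_len(reps)) {
      at <- alpha_topic %||% (50 / k)
      m <- fit_btm(corpus, k, alpha_topic = at, beta_word = beta_word,
                   n_iter = n_iter, seed = seed_fn(k, r))
      ss <- specificity_score(m$theta_doc)
      ps <- purity_score(m$theta_doc)
      cmb <- combination_score(ss, ps)
      cand <- list(model = m, ss = ss, ps = ps,
                   alpha = cmb$alpha, cs = cmb$cs)
      if (is.null(best_k) || cand$cs > best_k$cs) best_k <- cand
    }
    models[[as.character(k)]] <- best_k$model
    rows[[as.character(k)]] <- data.frame(k = k, ss = best_k$ss, ps = best_k$ps,
                                          alpha = best_k$alpha, cs = best_k$cs)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  best_i <- which.max(report$cs)  # first max -> smaller k on ties
  report$chosen <- seq_len(nrow(report)) == best_i
  list(model = models[[as.character(report$k[best_i])]], report = report)
}

#' UMass topic coherence of the top words of each topic
#'
#' For each topic, takes the `top_n` words ranked by occurrence
#' probability and sums `log((Dcooc(w_i, w_j) + 1) / Ddoc(w_j))` over
#' ranked pairs i < j, where `Dcooc` counts documents containing both
#' words and `Ddoc` counts documents containing the later-ranked word.
#' Near-zero values indicate topics whose top words co-occur in the same
#' documents; strongly negative values indicate incoherent topics.
#'
#' @param model a `TopicModel`.
#' @param corpus the `Corpus` it was fitted to.
#' @param top_n number of top words per topic (default 5).
#' @return numeric vector of per-topic coherence scores.
#' @export
topic_coherence <- function(model, corpus, top_n = 5) {
  V <- length(corpus$vocab)
  top_n <- min(top_n, V)
  doc_has <- matrix(FALSE, nrow = length(corpus$docs), ncol = V)
  for (d in seq_along(corpus$docs)) doc_has[d, corpus$docs[[d]]] <- TRUE
  ddoc <- colSums(doc_has)
  vapply(seq_len(model$k), function(t) {
    top <- order(-model$phi[t, ], seq_len(V))[seq_len(top_n)]
    if (top_n < 2) return(0)
    s <- 0
    for (i in 1:(top_n - 1)) for (j in (i + 1):top_n) {
      dcooc <- sum(doc_has[, top[i]] & doc_has[, top[j]])
      s <- s + log((dcooc + 1) / max(ddoc[top[j]], 1))
    }
    s
  }, numeric(1))
}

#' Dump a topic model's word distributions
#'
#' @param model a `TopicModel`.
#' @param path output TSV path (topics x words).
#' @export
write_topic_tsv <- function(model, path) {
  df <- data.frame(topic = seq_len(model$k), model$phi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
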