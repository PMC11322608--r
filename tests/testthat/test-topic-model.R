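# Corpus fixture: documents given directly as word-id lists over a vocab.
make_corpus <- function(docs, vocab) {
  bt <- list(); dof <- list()
  for (d in seq_along(docs)) {
    w <- docs[[d]]
    if (length(w) >= 2) {
      pairs <- utils::combn(w, 2)
      bt[[length(bt) + 1]] <- t(pairs)
      dof[[length(dof) + 1]] <- rep(d, ncol(pairs))
    }
  }
  structure(list(vocab = vocab, docs = docs,
                 biterms = if (length(bt)) do.call(rbind, bt)
                           else matrix(integer(0), ncol = 2),
                 doc_of = if (length(dof)) unlist(dof) else integer(0),
                 bins = seq_along(docs)),
            class = "Corpus")
}

# Two planted word communities, n docs each.
community_corpus <- function(n_per = 200, w_per_doc = 3, seed = 1) {
  set.seed(seed)
  docs <- c(lapply(seq_len(n_per), function(i) sort(sample(1:5, w_per_doc))),
            lapply(seq_len(n_per), function(i) sort(sample(6:10, w_per_doc))))
  make_corpus(docs, vocab = LETTERS[1:10])
}

test_that("corpus construction enumerates biterms with multiplicity", {
  gb_docs <- list(c(1L, 2L, 3L), 1L, c(1L, 2L), c(1L, 2L))
  corp <- make_corpus(gb_docs, LETTERS[1:3])
  # {A,B,C} -> AB, AC, BC; {A} -> none; two {A,B} docs -> AB twice
  expect_equal(nrow(corp$biterms), 5)
  expect_equal(sum(corp$biterms[, 1] == 1 & corp$biterms[, 2] == 2), 3)

  # corpus_from_segment agrees on an occupancy-backed segment
  m <- matrix(0, 4, 3, dimnames = list(NULL, c("A", "B", "F")))
  m[1, ] <- c(1, 1, 1); m[2, ] <- c(1, 0, 1); m[3, ] <- c(0, 1, 1)
  m[4, "F"] <- 1
  occ <- toy_occupancy(m)
  seg <- structure(list(focus = "F", members = c("A", "B"),
                        beta = c(A = .5, B = .5), gamma = c(A = 1, B = 1),
                        caps = c("A", "B", "F"), bins = 1:4,
                        delta = rep(1, 4), context = "unsplit"),
                   class = "Segment")
  corp2 <- corpus_from_segment(seg, occ)
  expect_equal(length(corp2$docs), 4)
  expect_equal(nrow(corp2$biterms), 3 + 1 + 1 + 0)
})

test_that("fitted distributions are normalised and deterministic under a seed", {
  corp <- community_corpus(50, seed = 3)
  m <- fit_btm(corp, k = 3, n_iter = 100, seed = 9)
  expect_equal(rowSums(m$phi), rep(1, 3), tolerance = 1e-9)
  expect_equal(rowSums(m$theta_doc), rep(1, length(corp$docs)),
               tolerance = 1e-9)
  expect_true(all(m$phi >= 0) && all(m$theta_doc >= 0))
  m2 <- fit_btm(corp, k = 3, n_iter = 100, seed = 9)
  expect_identical(m$phi, m2$phi)
  expect_identical(m$theta_doc, m2$theta_doc)
  m3 <- fit_btm(corp, k = 3, n_iter = 100, seed = 10)
  expect_false(identical(m$phi, m3$phi))
})

test_that("single-topic fit on a two-word corpus matches closed-form counts", {
  # every document is {w1, w2}: with k = 1 all biterms land in topic 1,
  # phi = (N + beta) / (2N + 2 beta) for each word
  corp <- make_corpus(rep(list(c(1L, 2L)), 30), c("w1", "w2"))
  m <- fit_btm(corp, k = 1, beta_word = 0.01, n_iter = 10, seed = 1)
  expect_equal(unname(m$phi[1, ]), rep((30 + 0.01) / (60 + 0.02), 2),
               tolerance = 1e-12)
  expect_equal(m$theta_global, 1)
})

test_that("documents without biterms receive the global topic distribution", {
  docs <- c(rep(list(c(1L, 2L)), 10), list(3L))  # last doc: one word
  corp <- make_corpus(docs, c("a", "b", "c"))
  m <- fit_btm(corp, k = 2, n_iter = 50, seed = 4)
  expect_equal(unname(m$theta_doc[11, ]), m$theta_global, tolerance = 1e-12)
})

test_that("planted two-community corpus is recovered at k = 2", {
  hits <- 0
  for (s in 1:10) {
    corp <- community_corpus(200, seed = s)
    m2 <- fit_btm(corp, k = 2, n_iter = 200, seed = 100 + s)
    top1 <- order(-m2$phi[1, ])[1:5]
    top2 <- order(-m2$phi[2, ])[1:5]
    if (setequal(sort(top1), 1:5) && setequal(sort(top2), 6:10) ||
        setequal(sort(top1), 6:10) && setequal(sort(top2), 1:5))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("model selection arithmetic matches hand-computed values", {
  # one-hot alternating theta over k = 2, p = 4:
  # column mean 0.5, population variance 0.25 -> SS = log(1) = 0
  # row variance 0.25 each -> PS = log(0.25); alpha = 1, CS = 0
  th <- matrix(c(1, 0, 0, 1, 1, 0, 0, 1), 4, 2, byrow = TRUE)
  ss <- specificity_score(th)
  ps <- purity_score(th)
  expect_equal(ss, 0)
  expect_equal(ps, log(0.25))
  cmb <- combination_score(ss, ps)
  expect_equal(cmb$alpha, 1)
  expect_equal(cmb$cs, 0)

  # degenerate uniform theta floors at log(eps)
  un <- matrix(0.5, 4, 2)
  expect_equal(specificity_score(un), log(1e-12))
  expect_equal(purity_score(un), log(1e-12))
  expect_gt(purity_score(th), purity_score(un))

  # duplicating rows leaves SS unchanged (scale invariance in p)
  expect_equal(specificity_score(rbind(th, th)), ss)

  # direct arithmetic cases
  expect_equal(combination_score(2, 1),
               list(alpha = 1 / 3, cs = (1 / 3) * 2 + (2 / 3) * 1))
  expect_equal(combination_score(3, 3), list(alpha = 0.5, cs = 3))
  expect_equal(combination_score(1, -1)$alpha, 0.5)  # SS + PS = 0 convention
})

test_that("selection report has one row per k and breaks CS ties to smaller k", {
  corp <- community_corpus(30, seed = 2)
  sel <- select_topic_number(corp, k_range = 2:4, seed = 5, n_iter = 50)
  expect_equal(sel$report$k, 2:4)
  expect_equal(sum(sel$report$chosen), 1)
  expect_equal(sel$report$cs[sel$report$chosen], max(sel$report$cs))
})

test_that("UMass coherence counts document co-occurrence", {
  # topic top words always co-occur: sum over pairs of log((D+1)/D)
  docs <- rep(list(c(1L, 2L, 3L)), 20)
  corp <- make_corpus(docs, c("a", "b", "c"))
  m <- fit_btm(corp, k = 1, n_iter = 20, seed = 1)
  co <- topic_coherence(m, corp, top_n = 3)
  expect_equal(co, 3 * log(21 / 20), tolerance = 1e-12)

  # never co-occurring top words: strongly negative
  docs2 <- c(rep(list(c(1L, 2L)), 10), rep(list(c(3L, 4L)), 10))
  corp2 <- make_corpus(docs2, c("a", "b", "c", "d"))
  m2 <- fit_btm(corp2, k = 1, n_iter = 20, seed = 1)
  co2 <- topic_coherence(m2, corp2, top_n = 4)
  expect_lt(co2, -5)

  expect_equal(topic_coherence(m, corp, top_n = 1), 0)
})

test_that("topic label permutation leaves scores and signatures unchanged", {
  corp <- community_corpus(100, seed = 6)
  m <- fit_btm(corp, k = 3, n_iter = 200, seed = 7)
  perm <- c(3L, 1L, 2L)
  mp <- m
  mp$phi <- m$phi[perm, ]
  mp$theta_doc <- m$theta_doc[, perm]
  mp$theta_global <- m$theta_global[perm]
  expect_equal(specificity_score(mp$theta_doc), specificity_score(m$theta_doc))
  expect_equal(purity_score(mp$theta_doc), purity_score(m$theta_doc))
  expect_setequal(topic_coherence(mp, corp), topic_coherence(m, corp))

  # downstream signature calling yields the same component sets
  m_occ <- matrix(0, length(corp$docs), 10,
                  dimnames = list(NULL, corp$vocab))
  for (d in seq_along(corp$docs)) m_occ[d, corp$docs[[d]]] <- 1
  occ <- toy_occupancy(m_occ)
  seg <- structure(list(focus = corp$vocab[1], members = corp$vocab[-1],
                        beta = NULL, gamma = NULL, caps = corp$vocab,
                        bins = seq_along(corp$docs),
                        delta = rep(1, length(corp$docs)),
                        context = "unsplit"),
                   class = "Segment")
  sig <- call_signatures(m, corp, seg, occ, min_positive = 1)
  sig_p <- call_signatures(mp, corp, seg, occ, min_positive = 1)
  comps <- lapply(sig, `[[`, "components")
  comps_p <- lapply(sig_p, `[[`, "components")
  expect_setequal(vapply(comps, paste, character(1), collapse = ","),
                  vapply(comps_p, paste, character(1), collapse = ","))
})
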