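# Minimal segment over an occupancy matrix for signature-calling tests.
seg_over <- function(occ, bins = seq_len(nrow(occ$O)), context = "unsplit") {
  caps <- occ$caps
  structure(list(focus = caps[length(caps)], members = caps[-length(caps)],
                 beta = NULL, gamma = NULL, caps = caps, bins = bins,
                 delta = rep(1, length(bins)), context = context),
            class = "Segment")
}

test_that("component calling applies the z > lambda rule to topic rows", {
  # phi row (0.5, 0.3, 0.1, 0.05, 0.05): only 0.5 has z = 1.70 > 1.3,
  # one component < min_components -> signature dropped
  phi <- rbind(c(0.5, 0.3, 0.1, 0.05, 0.05))
  caps <- LETTERS[1:5]
  colnames(phi) <- caps
  m <- structure(list(k = 1, phi = phi,
                      theta_doc = matrix(1, 4, 1), theta_global = 1),
                 class = "TopicModel")
  occ <- toy_occupancy(matrix(1, 4, 5, dimnames = list(NULL, caps)))
  corp <- corpus_from_segment(seg_over(occ), occ)
  sigs <- call_signatures(m, corp, seg_over(occ), occ,
                          min_components = 3, min_positive = 1)
  expect_length(sigs, 0)
  # the z arithmetic itself
  z <- (0.5 - 0.2) / sqrt(mean((phi[1, ] - 0.2)^2))
  expect_equal(z, 1.7039, tolerance = 1e-4)
  sigs1 <- call_signatures(m, corp, seg_over(occ), occ,
                           min_components = 1, min_positive = 1)
  expect_identical(sigs1[[1]]$components, "A")

  # uniform row: all z = 0, no components
  m$phi <- matrix(0.2, 1, 5, dimnames = list(NULL, caps))
  expect_length(call_signatures(m, corp, seg_over(occ), occ,
                                min_components = 1, min_positive = 1), 0)
})

test_that("positive bins require ceil(pos_frac * n_components) occupied components", {
  # components must be a minority of the vocabulary for all of them to
  # clear the z threshold (a 5-of-7 majority can never reach z > 1.3)
  caps <- c(LETTERS[1:5], paste0("x", 1:10), "F")
  m <- matrix(0, 6, 16, dimnames = list(NULL, caps))
  m[1, 1:5] <- 1          # 5 of 5
  m[2, 1:4] <- 1          # 4 of 5 -> 4 >= ceil(0.8*5) = 4: positive
  m[3, 1:3] <- 1          # 3 of 5 -> not positive
  m[4, c(1:4, 6)] <- 1    # 4 components + extra CAP: positive
  occ <- toy_occupancy(m)
  phi <- matrix(c(rep(0.15, 5), rep(0.25 / 11, 11)), 1, 16,
                dimnames = list(NULL, caps))  # z(0.15) ~ 1.48 > 1.3
  mod <- structure(list(k = 1, phi = phi, theta_doc = matrix(1, 6, 1),
                        theta_global = 1), class = "TopicModel")
  corp <- corpus_from_segment(seg_over(occ), occ)
  sigs <- call_signatures(mod, corp, seg_over(occ), occ,
                          min_components = 3, min_positive = 1)
  expect_identical(sigs[[1]]$components, LETTERS[1:5])
  expect_setequal(sigs[[1]]$pos_bins, c(1L, 2L, 4L))

  # min_positive threshold discards sparse signatures
  expect_length(call_signatures(mod, corp, seg_over(occ), occ,
                                min_components = 3, min_positive = 4), 0)
})

test_that("negative bins are comparably occupied but lack component co-occupancy", {
  caps <- c(LETTERS[1:5], "V", "W", "X", "Y", "F")
  m <- matrix(0, 8, 10, dimnames = list(NULL, caps))
  m[1, 1:5] <- 1               # positive bin
  m[2, c(1, 6:8)] <- 1         # 4 occupied, 1 component -> negative
  m[3, c(1, 2, 6, 7)] <- 1     # 4 occupied, 2 components -> excluded
  m[4, 6:8] <- 1               # 3 occupied < h = 4 -> not negative
  m[5, 6:9] <- 1               # 4 occupied, 0 components -> negative
  occ <- toy_occupancy(m)
  sig <- structure(list(id = "s", focus = "F", context = "unsplit",
                        topic = 1, components = LETTERS[1:5],
                        z_scores = NULL, phi_probs = NULL,
                        pos_bins = 1L, caps = caps),
                   class = "Signature")
  neg <- define_negative_bins(sig, occ, context_bins = 1:8)
  expect_setequal(neg, c(2L, 5L))
})

test_that("per-bin condensation features match their definitions", {
  caps <- c("A", "B", "C", "D")
  ann <- toy_annotations(caps, llps = c("A", "B"),
                         idr = c("A", "B", "C", "D"), rbp = "C",
                         mlo = list(nucleolus = c("A", "B"), speckle = "C"),
                         ppi = cbind("A", "B"))
  m <- matrix(0, 3, 4, dimnames = list(NULL, caps))
  m[1, ] <- 1                # all four occupied
  m[2, 1:3] <- 1             # A, B, C
  m[3, 1] <- 1               # single CAP
  occ <- toy_occupancy(m)
  f <- compute_features(1:3, occ, caps, ann, rbs = c(1.5, 0, 0))
  expect_equal(f$F_LLPS, c(0.5, 2 / 3, 1))
  expect_equal(f$F_IDR, c(1, 1, 1))
  expect_equal(f$F_RBP, c(0.25, 1 / 3, 0))
  # best single MLO: nucleolus holds A and B
  expect_equal(f$F_MLO, c(0.5, 2 / 3, 1))
  # one PPI edge among C(4,2)=6 and C(3,2)=3 pairs; <2 occupied -> 0
  expect_equal(f$F_PPI, c(1 / 6, 1 / 3, 0))
  expect_equal(f$S_RBS, c(1.5, 0, 0))
  expect_equal(f$n_occupied, c(4L, 3L, 1L))

  # zero occupied CAPs -> all-NA feature row
  m0 <- m; m0[3, ] <- 0
  f0 <- compute_features(1:3, toy_occupancy(m0), caps, ann)
  expect_true(all(is.na(f0[3, c("F_LLPS", "F_MLO", "F_IDR", "F_PPI", "F_RBP")])))
})

test_that("feature computation matches a brute-force oracle on random instances", {
  set.seed(21)
  for (i in 1:100) {
    nc <- sample(3:8, 1)
    caps <- paste0("c", seq_len(nc))
    ann <- toy_annotations(
      caps,
      llps = sample(caps, sample(0:nc, 1)),
      idr = sample(caps, sample(0:nc, 1)),
      rbp = sample(caps, sample(0:nc, 1)),
      mlo = list(m1 = sample(caps, sample(0:nc, 1)),
                 m2 = sample(caps, sample(0:nc, 1))),
      ppi = if (nc >= 2) {
        prs <- t(utils::combn(caps, 2))
        prs[sample(nrow(prs), sample(0:min(4, nrow(prs)), 1)), , drop = FALSE]
      } else NULL)
    occ_row <- rbinom(nc, 1, 0.6)
    if (sum(occ_row) == 0) occ_row[sample(nc, 1)] <- 1
    m <- matrix(occ_row, 1, nc, dimnames = list(NULL, caps))
    f <- compute_features(1L, toy_occupancy(m), caps, ann)
    on <- caps[occ_row == 1]
    expect_equal(f$F_LLPS, sum(ann$is_llps[on]) / length(on), tolerance = 1e-12)
    expect_equal(f$F_IDR, sum(ann$has_idr[on]) / length(on), tolerance = 1e-12)
    expect_equal(f$F_RBP, sum(ann$is_rbp[on]) / length(on), tolerance = 1e-12)
    mlo_oracle <- max(0, vapply(c("m1", "m2"), function(mm)
      sum(vapply(on, function(cp) mm %in% ann$mlo_memberships[[cp]],
                 logical(1))) / length(on), numeric(1)))
    expect_equal(f$F_MLO, mlo_oracle, tolerance = 1e-12)
    ppi_oracle <- if (length(on) < 2) 0 else {
      prs <- utils::combn(on, 2)
      sum(vapply(seq_len(ncol(prs)), function(j)
        any(ann$ppi_edges[, 1] == min(prs[, j]) &
            ann$ppi_edges[, 2] == max(prs[, j])), logical(1))) /
        choose(length(on), 2)
    }
    expect_equal(f$F_PPI, ppi_oracle, tolerance = 1e-12)
  }
})

test_that("midrank AUROC equals the pairwise probability oracle", {
  expect_equal(auroc(c(2, 3), c(0, 1)), 1)
  expect_equal(auroc(c(1, 0), c(0, 1)), 0.5)  # (1 + 0.5 + 0.5 + 0) / 4
  x <- c(0.1, 0.4, 0.4, 0.9)
  expect_equal(auroc(x, x), 0.5)
  expect_error(auroc(numeric(0), 1), "non-empty")

  set.seed(33)
  for (i in 1:100) {
    pos <- sample(0:5, sample(2:10, 1), replace = TRUE) +
      round(runif(1), 2)
    neg <- sample(0:5, sample(2:10, 1), replace = TRUE)
    expect_equal(auroc(pos, neg), oracle_auroc(pos, neg), tolerance = 1e-12)
  }
})

test_that("CondSig filtration applies both AUROC criteria", {
  pass_rule <- function(aurocs, auroc_min = 0.6, mean_top3_min = 0.65) {
    passing <- sum(aurocs > auroc_min)
    mt3 <- mean(sort(aurocs, decreasing = TRUE)[1:3])
    passing >= 3 && mt3 > mean_top3_min
  }
  expect_true(pass_rule(c(0.70, 0.68, 0.66, 0.50, 0.50, 0.50)))   # mt3 = 0.68
  expect_false(pass_rule(c(0.70, 0.62, 0.61, 0.50, 0.50, 0.50)))  # mt3 ~ 0.643
  expect_false(pass_rule(c(0.90, 0.90, 0.55, 0.50, 0.50, 0.50)))  # 2 passing
})

test_that("scored signatures separate enriched positives from negatives", {
  set.seed(77)
  caps <- c(LETTERS[1:5], paste0("b", 1:5))
  # 60 positive bins occupied by A..E; 60 negatives by the b-CAPs
  m <- matrix(0, 130, 10, dimnames = list(NULL, caps))
  for (i in 1:60) m[i, sample(1:5, 4)] <- 1
  for (i in 61:120) m[i, 5 + sample(1:5, 4)] <- 1
  m[121:130, sample(10, 3)] <- 1
  occ <- toy_occupancy(m)
  ann <- toy_annotations(caps, llps = LETTERS[1:4], idr = LETTERS[1:5],
                         rbp = LETTERS[2:5],
                         mlo = list(body = LETTERS[1:5]),
                         ppi = t(utils::combn(LETTERS[1:5], 2)))
  sig <- structure(list(id = "s", focus = "A", context = "unsplit",
                        topic = 1, components = LETTERS[1:5],
                        z_scores = stats::setNames(rep(2, 5), LETTERS[1:5]),
                        phi_probs = stats::setNames(rep(0.19, 10), caps),
                        pos_bins = which(rowSums(m[, 1:5]) >= 4),
                        caps = caps),
                   class = "Signature")
  out <- score_signatures(list(sig), occ, ann, promoter_map = rep(TRUE, 130))
  cs <- out[[1]]
  expect_true(cs$is_condsig)
  expect_gte(length(cs$passing), 3)
  expect_true(all(cs$aurocs[cs$passing] > 0.6))
  expect_gt(cs$mean_top3, 0.65)
  # positive, negative and excluded bins partition the context universe
  expect_length(intersect(cs$pos_bins, cs$neg_bins), 0)

  # empty negative pool -> warned, scored as non-CondSig
  sig2 <- sig; sig2$pos_bins <- 1:130
  expect_warning(out2 <- score_signatures(list(sig2), occ, ann,
                                          promoter_map = rep(TRUE, 130)),
                 "no negative bins")
  expect_false(out2[[1]]$is_condsig)
})

test_that("deduplication enforces the top-5 Jaccard contract", {
  a <- toy_condsig("a", LETTERS[1:5], mean_top3 = 0.9)
  b <- toy_condsig("b", LETTERS[1:5], mean_top3 = 0.8)     # identical top-5
  c3 <- toy_condsig("c", c("A", "B", "C", "X", "Y"), mean_top3 = 0.85)
  d <- toy_condsig("d", c("P", "Q", "R", "S", "T"), mean_top3 = 0.7)
  out <- deduplicate(list(a, b, c3, d))
  ids <- vapply(out, `[[`, character(1), "id")
  expect_true("a" %in% ids)       # highest scoring of the redundant set
  expect_false("b" %in% ids)      # Jaccard 1 with a
  expect_false("c" %in% ids)      # Jaccard 3/7 > 0.25 with a, lower score
  expect_true("d" %in% ids)       # disjoint

  # pairwise top-5 Jaccard <= 0.25 on many random pools
  set.seed(55)
  pool_caps <- paste0("c", 1:12)
  for (rep in 1:40) {
    sigs <- lapply(1:25, function(i)
      toy_condsig(paste0("s", i), sample(pool_caps, 5),
                  mean_top3 = runif(1, 0.65, 1)))
    out <- deduplicate(sigs)
    tops <- lapply(out, function(cs) cs$components)
    if (length(out) >= 2) {
      prs <- utils::combn(length(out), 2)
      jac <- vapply(seq_len(ncol(prs)), function(j)
        length(intersect(tops[[prs[1, j]]], tops[[prs[2, j]]])) /
          length(union(tops[[prs[1, j]]], tops[[prs[2, j]]])), numeric(1))
      expect_true(all(jac <= 0.25))
    }
  }
})

test_that("merged positive sites join book-ended bins", {
  m <- matrix(1, 6, 2, dimnames = list(NULL, c("A", "B")))
  occ <- toy_occupancy(m)
  cs1 <- toy_condsig("a", c("A", "B"), pos_bins = c(1L, 2L, 5L))
  sites <- positive_sites(list(cs1), occ)
  expect_equal(length(sites), 2)
  expect_equal(GenomicRanges::width(sites), c(2000, 1000))
})
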