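test_that("relevance ranking puts a label copy first and constants last", {
  set.seed(2)
  y <- rep(c(0, 1), each = 10)
  x <- cbind(noise1 = rnorm(20), label_copy = y + 0.0, noise2 = rnorm(20),
             const = rep(1, 20))
  r <- rank_by_relevance(x, y)
  expect_equal(r$feature[1], "label_copy")
  expect_equal(r$score[length(r$score)], 0)
  expect_equal(r$feature[4], "const")
  # full ranking is a permutation of all features
  expect_setequal(r$index, 1:4)
  expect_error(rank_by_relevance(x, y, n = 5), "n must be")
})

test_that("relevance ranking matches a score-then-sort oracle on random instances", {
  for (seed in 1:5) {
    inst <- random_binary_instance(n = 30, p = 30, seed = seed)
    r <- rank_by_relevance(inst$x, inst$y)
    scores <- round(vapply(seq_len(30), function(j)
      oracle_mi(oracle_discretize(inst$x[, j], 10), inst$y), numeric(1)), 10)
    expect_equal(r$index, order(-scores, seq_len(30)))
    expect_equal(r$score, scores[r$index], tolerance = 1e-12)
    expect_true(all(diff(r$score) <= 1e-12))
  }
})

test_that("FCBF keeps one of two label copies and drops noise below delta", {
  set.seed(4)
  y <- rep(c(0, 1), each = 12)
  x <- cbind(copy_a = as.numeric(y), copy_b = as.numeric(y),
             noise = rnorm(24))
  res <- fcbf_select(x, y, delta = 0.1)
  expect_equal(res$feature, "copy_a")   # tie between copies -> lower index
  expect_equal(unname(res$score), 1)
})

test_that("FCBF with delta 0 keeps independent informative features", {
  # four mutually independent binary features, each partially predictive
  y <- rep(c(0L, 1L), each = 8)
  set.seed(6)
  x <- sapply(1:4, function(j) {
    flip <- rbinom(16, 1, 0.2)
    as.numeric(xor(y, flip))
  })
  colnames(x) <- paste0("f", 1:4)
  res <- fcbf_select(x, y, delta = 0)
  # independent features rarely dominate each other; all should survive
  expect_gte(nrow(res), 3)
})

test_that("FCBF errors when every feature is below delta", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c(0, 1), each = 10)
  expect_error(fcbf_select(x, y, delta = 0.99), "maximum observed SU")
})

test_that("FCBF matches the all-ordered-pairs brute force on random instances", {
  for (seed in 1:20) {
    inst <- random_binary_instance(n = 40, p = 12, seed = seed)
    for (delta in c(0, 0.05)) {
      got <- fcbf_select(inst$x, inst$y, delta = delta)
      expect_equal(got$index, oracle_fcbf(inst$x, inst$y, delta),
                   info = paste("seed", seed, "delta", delta))
    }
  }
})

test_that("FCBF survivors are invariant to feature-order permutation", {
  inst <- random_binary_instance(n = 40, p = 10, seed = 3)
  base <- fcbf_select(inst$x, inst$y, delta = 0)
  set.seed(99)
  perm <- sample.int(10)
  xp <- inst$x[, perm]
  res <- fcbf_select(xp, inst$y, delta = 0)
  # same features survive (tie rule acts on original index, which permutes)
  expect_setequal(res$feature, base$feature)
})

test_that("size-targeted FCBF honours the target and flags short sets", {
  inst <- random_binary_instance(n = 40, p = 12, seed = 8)
  full <- fcbf_select(inst$x, inst$y, delta = 0)
  # n = 1 returns the single top-SU survivor
  one <- fcbf_select_n(inst$x, inst$y, n = 1)
  expect_equal(one$feature, full$feature[1])
  # n beyond what delta = 0 achieves returns the full set, flagged short
  big <- fcbf_select_n(inst$x, inst$y, n = 12)
  if (nrow(full) < 12) {
    expect_equal(big$index, full$index)
    expect_true(attr(big, "short"))
  }
})

test_that("size-targeted FCBF finds the largest achievable count <= n over the delta grid", {
  for (seed in 1:3) {
    inst <- random_binary_instance(n = 40, p = 20, seed = seed)
    n <- 5
    got <- fcbf_select_n(inst$x, inst$y, n = n)
    # oracle: sweep every observed SU(c; f) value as delta
    dx <- lapply(seq_len(20), function(j) oracle_discretize(inst$x[, j], 10))
    su_c <- round(vapply(dx, function(c1) oracle_su(c1, inst$y), numeric(1)), 10)
    counts <- vapply(sort(unique(su_c)), function(delta) {
      length(oracle_fcbf(inst$x, inst$y, delta))
    }, numeric(1))
    best <- max(counts[counts <= n], 0)
    expect_lte(nrow(got), n)
    expect_equal(nrow(got), best)
  }
})

test_that("mRMR at n = 1 reduces to max relevance", {
  inst <- random_binary_instance(seed = 12)
  expect_equal(mrmr_select(inst$x, inst$y, n = 1)$feature,
               rank_by_relevance(inst$x, inst$y, n = 1)$feature)
})

test_that("mRMR penalizes a duplicated feature in favour of weaker independent signal", {
  # strong = a slightly noisy label surrogate, duplicated exactly; weak = an
  # independently noisy surrogate. The duplicate's redundancy with the first
  # pick (its own entropy) exceeds its relevance, so the weak independent
  # feature must be picked second.
  set.seed(13)
  y <- rep(c(0, 1), each = 15)
  strong <- as.numeric(xor(y, rbinom(30, 1, 0.05)))
  weak <- as.numeric(xor(y, rbinom(30, 1, 0.25)))
  x <- cbind(copy_a = strong, copy_b = strong, weak = weak)
  sel <- mrmr_select(x, y, n = 2)
  expect_equal(sel$feature, c("copy_a", "weak"))
})

test_that("mRMR matches the per-step exhaustive oracle", {
  for (seed in 1:20) {
    inst <- random_binary_instance(n = 40, p = 12, seed = seed)
    got <- mrmr_select(inst$x, inst$y, n = 5, window = 12)
    expect_equal(got$index, oracle_mrmr(inst$x, inst$y, 5),
                 info = paste("seed", seed))
  }
})

test_that("mRMR selections nest as n grows and the window caps the pool", {
  inst <- random_binary_instance(n = 40, p = 20, seed = 21)
  prev <- character(0)
  for (n in 1:6) {
    cur <- mrmr_select(inst$x, inst$y, n = n, window = 20)$feature
    expect_equal(cur[seq_along(prev)], prev)   # greedy nesting
    prev <- cur
  }
  expect_error(mrmr_select(inst$x, inst$y, n = 10, window = 5), "pool")
  # pool restriction: all picks come from the top-w by relevance
  w <- 8
  pool <- rank_by_relevance(inst$x, inst$y, n = w)$index
  got <- mrmr_select(inst$x, inst$y, n = 5, window = w)
  expect_true(all(got$index %in% pool))
})

test_that("set-level relevance and redundancy diagnostics are consistent", {
  inst <- random_binary_instance(n = 40, p = 6, seed = 30)
  feats <- c(1, 2, 3)
  d <- subset_relevance(inst$x, inst$y, feats)
  dx <- lapply(feats, function(j) oracle_discretize(inst$x[, j], 10))
  expect_equal(d, mean(vapply(dx, function(c1) oracle_mi(c1, inst$y),
                              numeric(1))), tolerance = 1e-12)
  r <- subset_redundancy(inst$x, inst$y, feats)
  tot <- 0
  for (i in 1:3) for (j in 1:3) tot <- tot + oracle_mi(dx[[i]], dx[[j]])
  expect_equal(r, tot / 9, tolerance = 1e-12)
  # duplicated features are maximally redundant
  x2 <- cbind(a = inst$x[, 1], b = inst$x[, 1])
  expect_gt(subset_redundancy(x2, inst$y, c("a", "b")),
            subset_redundancy(inst$x, inst$y, c(1, 4)))
})
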