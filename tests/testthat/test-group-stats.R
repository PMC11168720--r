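# Wilcoxon maps, cluster permutation, normality screen, trends

test_that("exact signed-rank p matches full enumeration for n <= 12", {
  set.seed(61)
  for (n in 4:12) {
    for (rep in 1:3) {
      d <- rnorm(n)
      if (rep == 2) d <- round(d) + 0.5 * sign(d)     # forced rank ties
      if (rep == 3) d[1:2] <- abs(d[1:2])
      d <- d[d != 0]
      expect_equal(signed_rank_test(d)$p, enum_signed_rank_p(d))
    }
  }
  # the classic small-n landmarks
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5, 6) + 0.1)$p, 0.03125)
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5))$p, 0.0625)
})

test_that("signed-rank agrees with stats::wilcox.test on both branches", {
  set.seed(62)
  d <- rnorm(15)
  expect_equal(signed_rank_test(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value)
  d2 <- rnorm(40) + 0.3
  expect_equal(signed_rank_test(d2)$p,
               stats::wilcox.test(d2, exact = FALSE, correct = TRUE)$p.value)
})

test_that("zeros are dropped and all-zero samples degrade gracefully", {
  r <- signed_rank_test(c(0, 0, 1, 2, 3, 4, 5, 6))
  expect_equal(r$n_zero, 2L)
  expect_equal(r$p, 0.03125)
  r0 <- signed_rank_test(rep(0, 10))
  expect_equal(r0$p, 1)
  expect_equal(r0$sign, 0)
})

test_that("Shapiro screen recommends nonparametric testing for heavy tails", {
  set.seed(63)
  heavy <- matrix(rt(38 * 10, df = 1), 38, 10)
  s <- shapiro_wilk_screen(heavy)
  expect_true(s$recommend_nonparametric)
  normal <- matrix(rnorm(38 * 10), 38, 10)
  s2 <- shapiro_wilk_screen(normal)
  expect_false(s2$recommend_nonparametric)
  const <- cbind(rep(1, 38), rnorm(38))
  s3 <- shapiro_wilk_screen(const)
  expect_true(s3$flagged[1])
  expect_false(s3$flagged[2])
})

test_that("type-I rate of the Shapiro screen is near nominal for normal data", {
  set.seed(64)
  rej <- replicate(400, stats::shapiro.test(rnorm(38))$p.value < 0.05)
  expect_equal(mean(rej), 0.05, tolerance = 0.5)
})

line_adj <- function(k) {
  A <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) A[i, i + 1] <- A[i + 1, i] <- TRUE
  dimnames(A) <- list(letters[1:k], letters[1:k])
  A
}

test_that("size-1 clusters are discarded and contiguity is respected", {
  set.seed(65)
  k <- 4
  A <- line_adj(k)
  base <- matrix(rnorm(20 * k), 20, k, dimnames = list(NULL, letters[1:k]))
  # strong effect only in channel a (isolated under min_cluster = 2)
  post <- base; post[, 1] <- post[, 1] - 3
  m <- cluster_permutation_correct(
    wilcoxon_paired_map(base, post, alpha = 0.01), A, n_perm = 200, seed = 1)
  expect_true(m$raw_significant[1])
  expect_false(any(m$corrected_significant))

  # adjacent pair b, c forms one eligible cluster
  post2 <- base; post2[, 2:3] <- post2[, 2:3] - 3
  m2 <- cluster_permutation_correct(
    wilcoxon_paired_map(base, post2, alpha = 0.01), A, n_perm = 200, seed = 1)
  expect_true(all(m2$corrected_significant[2:3]))
  expect_equal(m2$cluster_id[2], m2$cluster_id[3])
  expect_false(any(m2$corrected_significant[c(1, 4)]))
})

test_that("opposite-signed neighbours do not merge into one cluster", {
  set.seed(66)
  A <- line_adj(4)
  base <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, letters[1:4]))
  post <- base
  post[, 2] <- post[, 2] - 3
  post[, 3] <- post[, 3] + 3
  m <- wilcoxon_paired_map(base, post, alpha = 0.01)
  mc <- cluster_permutation_correct(m, A, n_perm = 200, seed = 2)
  expect_true(all(m$raw_significant[2:3]))
  expect_false(mc$cluster_id[2] == mc$cluster_id[3])
})

test_that("permutation guardrails hold", {
  A <- line_adj(3)
  base <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, letters[1:3]))
  m <- wilcoxon_paired_map(base, base + rnorm(30))
  expect_error(cluster_permutation_correct(m, A, n_perm = 50), "unstable")
  expect_error(wilcoxon_paired_map(base[1:4, ], base[1:4, ]), "6 paired")
})

test_that("corrected significance implies raw significance (invariant)", {
  set.seed(67)
  xy <- montage_1020()
  A <- channel_adjacency(xy)
  for (i in 1:5) {
    pre <- matrix(rnorm(38 * 29, 0, 1), 38, 29, dimnames = list(NULL, xy$label))
    post <- pre + matrix(rnorm(38 * 29, 0, 0.5), 38, 29)
    post[, sample(29, 6)] <- post[, sample(29, 6)] - 0.5
    m <- cluster_permutation_correct(wilcoxon_paired_map(pre, post), A,
                                     n_perm = 150, seed = i)
    expect_true(all(!m$corrected_significant | m$raw_significant))
    # clusters surviving correction have at least the minimum size
    if (any(m$corrected_significant)) {
      sz <- table(m$cluster_id[m$corrected_significant])
      expect_true(all(sz >= attr(m, "min_cluster")))
    }
  }
})

test_that("z-scored trends are affine-invariant and centred per event", {
  M <- rbind(seq(1, 20), seq(5, 100, by = 5))
  tz <- trend_zscore(M)
  expect_equal(mean(tz$trend), 0, tolerance = 1e-12)
  # per-event affine rescaling leaves the group trend unchanged
  tz2 <- trend_zscore(M * c(3, 0.1) + c(100, -2))
  expect_equal(tz$trend, tz2$trend)
  # shared pre-high/post-low step shows in the trend signs
  set.seed(68)
  S <- cbind(matrix(rnorm(10 * 10, 1, 0.1), 10), matrix(rnorm(10 * 10, -1, 0.1), 10))
  tzs <- trend_zscore(S)
  expect_true(all(tzs$trend[1:10] > 0) && all(tzs$trend[11:20] < 0))
  expect_warning(trend_zscore(rbind(M, rep(1, 20))), "zero within-event")
})

test_that("surrogate window placement leaves a gap and respects data limits", {
  w <- surrogate_windows(3600 + 60 + 600 + 100, window_min = 5)
  expect_equal(diff(w$preictal), 300)
  expect_equal(diff(w$postictal), 300)
  expect_equal(w$postictal[1] - w$preictal[2], 60)
  expect_equal(3600 + 60 + 600 + 100 - w$postictal[2], 3600)
  short <- surrogate_windows(1800, window_min = 5)
  expect_true(short$excluded)
})
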