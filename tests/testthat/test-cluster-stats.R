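# Wilcoxon z, cluster finding, permutation test, proportion test, summaries.

test_that("wilcoxon_z matches closed-form moments and handles edge cases", {
  # n = 10, all positive: W+ = 55, z = 27.5 / sqrt(96.25)
  d <- (1:10) / 10
  expect_equal(wilcoxon_z(d), 27.5 / sqrt(96.25), tolerance = 1e-12)
  # mirror-symmetric differences: W+ = n(n+1)/4 exactly
  expect_equal(wilcoxon_z(c(-3, -1, 1, 3)), 0, tolerance = 1e-12)
  expect_warning(z0 <- wilcoxon_z(rep(0, 6)), "zero")
  expect_equal(z0, 0)
  # sign convention: mostly positive differences give positive z
  expect_gt(wilcoxon_z(c(5, 4, 3, 2, 1, -0.5)), 0)
})

test_that("wilcoxon_z agrees with exact sign-pattern enumeration for n <= 12", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n, mean = runif(1, -0.5, 1)), 2)
    d <- d[d != 0]
    if (length(d) < 6) next
    p_exact <- oracle_signed_rank_p(d)
    p_norm <- pnorm(wilcoxon_z(d), lower.tail = FALSE)
    # normal approximation error at these n stays within a few percent
    expect_lt(abs(p_norm - p_exact), 0.05)
  }
})

test_that("the signed-rank permutation decomposition reproduces per-bin z", {
  set.seed(32)
  D <- matrix(rnorm(40 * 25, 0.3), 40, 25)
  D[sample(length(D), 30)] <- 0          # some exact zeros
  M <- seegerd:::signed_rank_prep(D)
  z_direct <- suppressWarnings(apply(D, 2, wilcoxon_z))
  expect_equal(colSums(M), z_direct, tolerance = 1e-12)
  # a sign flip of trial i is the same as recomputing from flipped data
  s <- sample(c(-1, 1), 40, replace = TRUE)
  z_flip <- suppressWarnings(apply(D * s, 2, wilcoxon_z))
  expect_equal(as.vector(s %*% M), z_flip, tolerance = 1e-12)
})

test_that("cluster finding matches hand-enumerated examples", {
  cl <- find_clusters(c(2.0, 2.5, 1.0, 3.0), 1.96, "two")
  expect_equal(cl$start, c(1, 4))
  expect_equal(cl$end, c(2, 4))
  expect_equal(cl$mass, c(4.5, 3.0))
  expect_equal(nrow(find_clusters(c(1, -1.5, 0.3), 1.96, "two")), 0)
  # sign break splits a run
  cl2 <- find_clusters(c(2.0, -2.5), 1.96, "two")
  expect_equal(cl2$mass, c(2.0, -2.5))
  # one-tailed ignores negative excursions entirely
  cl3 <- find_clusters(c(-4, 2, 2, -4), 1.645, "one")
  expect_equal(cl3$start, 2)
  expect_equal(cl3$mass, 4)
  expect_error(find_clusters(c(1, 2), -1, "two"), "positive")
})

test_that("cluster finding agrees with brute force on exhaustive toy inputs", {
  # exhaustive 3-state patterns on 8 bins here (the 12-bin exhaustive sweep
  # runs in the acceptance suite)
  vals <- c(-2.5, 0.5, 2.5)
  grid <- as.matrix(expand.grid(rep(list(1:3), 8)))
  for (r in seq_len(nrow(grid))) {
    z <- vals[grid[r, ]]
    for (tl in c("one", "two")) {
      thr <- if (tl == "one") 1.645 else 1.96
      a <- find_clusters(z, thr, tl)
      b <- oracle_clusters(z, thr, tl)
      if (!identical(as.integer(a$start), as.integer(b$start)) ||
          !identical(as.integer(a$end), as.integer(b$end)) ||
          !isTRUE(all.equal(a$mass, b$mass))) {
        fail(sprintf("mismatch on pattern %s (%s-tailed)",
                     paste(z, collapse = ","), tl))
      }
    }
  }
  succeed()
})

test_that("permutation test degenerates correctly and is seed-deterministic", {
  set.seed(33)
  A <- matrix(rexp(20 * 30), 20)
  freqs <- seq(13, 30, length.out = 30)
  # identical data: all differences zero -> no clusters, p = 1
  ct0 <- cluster_permutation_test(A, A, tail = "two", n_perm = 100, seed = 1,
                                  freqs = freqs)
  expect_equal(ct0$p_value, 1)
  expect_equal(nrow(ct0$clusters), 0)
  # determinism
  B <- matrix(rexp(20 * 30), 20)
  c1 <- cluster_permutation_test(A, B, tail = "two", n_perm = 200, seed = 7,
                                 freqs = freqs)
  c2 <- cluster_permutation_test(A, B, tail = "two", n_perm = 200, seed = 7,
                                 freqs = freqs)
  expect_identical(c1$p_value, c2$p_value)
  expect_identical(c1$null_stats, c2$null_stats)
  expect_true(c1$p_value >= 1 / 201 && c1$p_value <= 1)
  expect_error(cluster_permutation_test(A, B, n_perm = 10, seed = 1,
                                        freqs = freqs + 100), "band")
})

test_that("one-tailed tests never report an opposite-sign cluster", {
  set.seed(34)
  for (i in 1:10) {
    # strong effect in the wrong direction: b >> a
    A <- matrix(rexp(25 * 30), 25)
    B <- matrix(rexp(25 * 30) * 3, 25)
    ct <- cluster_permutation_test(A, B, tail = "one", n_perm = 100,
                                   seed = i, freqs = seq(13, 30, length.out = 30))
    expect_equal(nrow(ct$clusters), 0)
    expect_equal(ct$p_value, 1)
    expect_false(ct$significant)
  }
})

test_that("proportion test matches prop.test and handles degeneracies", {
  pt <- proportion_test(10, 20, 10, 20)
  expect_equal(pt$z, 0)
  expect_equal(pt$p_value, 1)
  pt2 <- proportion_test(20, 20, 0, 20)
  expect_lt(pt2$p_value, 0.001)
  # oracle equivalence: z^2 equals the Yates chi-square
  for (cnt in list(c(20, 20, 0, 20), c(31, 64, 38, 85), c(47, 64, 58, 85),
                   c(5, 40, 12, 33))) {
    pt3 <- proportion_test(cnt[1], cnt[2], cnt[3], cnt[4])
    or <- suppressWarnings(prop.test(c(cnt[1], cnt[3]), c(cnt[2], cnt[4])))
    expect_equal(pt3$z^2, unname(or$statistic), tolerance = 1e-10)
    expect_equal(pt3$p_value, or$p.value, tolerance = 1e-10)
  }
  expect_error(proportion_test(5, 4, 1, 10), "invalid input")
  expect_error(proportion_test(1, 0, 1, 10), "invalid input")
})

test_that("modulation summary aggregates per participant and hemisphere", {
  contacts <- data.frame(
    contact_id = c("a", "b", "c", "d"),
    shaft_id = "s1", index_on_shaft = 0:3,
    tissue = c("gray", "gray", "gray", "white"),
    hemisphere = c("left", "left", "right", "right"),
    laterality = c("contralateral", "contralateral", "ipsilateral", "ipsilateral"),
    participant_id = "p01", stringsAsFactors = FALSE)
  mk <- function(sig, lo = 15, hi = 25, p = 0.01) {
    structure(list(significant = sig, p_value = p,
                   significant_range = if (sig) c(lo, hi) else NULL),
              class = "cluster_test")
  }
  res <- list(a = mk(TRUE, 13, 30, 0.03), b = mk(FALSE), c = mk(TRUE, 20, 30))
  ms <- summarize_modulation(res, contacts)
  left <- ms[ms$hemisphere == "left" & ms$participant == "p01", ]
  expect_equal(left$n_contacts, 2)
  expect_equal(left$pct_significant, 50)
  expect_equal(left$avg_freq, (13 + 30) / 2)
  expect_equal(left$max_p, 0.03)
  right <- ms[ms$hemisphere == "right" & ms$participant == "p01", ]
  expect_equal(right$pct_significant, 100)   # white-matter contact excluded
  expect_equal(right$freq_lo, 20)
  avg <- ms[ms$participant == "avg", ]
  expect_equal(avg$pct_significant, 75)
  # no significant contacts: zero percentage, NA markers
  ms0 <- summarize_modulation(list(a = mk(FALSE), b = mk(FALSE), c = mk(FALSE)),
                              contacts)
  expect_true(all(ms0$pct_significant == 0))
  expect_true(all(is.na(ms0$avg_freq)))
})
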