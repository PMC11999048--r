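test_that("stitch_peaks merges at the threshold boundary", {
  p <- peaks_df("chr1", c(0, 200), c(100, 300), score = c(1, 2))
  merged <- stitch_peaks(p, 100)  # gap is exactly 100 -> merge
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 300)
  expect_equal(merged$score, 3)
  expect_equal(merged$n_members, 2L)

  two <- stitch_peaks(p, 99)
  expect_equal(nrow(two), 2L)

  # distance 0: only overlapping/abutting peaks merge
  p3 <- peaks_df("chr1", c(0, 100, 201), c(100, 150, 300), score = 1)
  expect_equal(stitch_peaks(p3, 0)$n_members, c(2L, 1L))
})

test_that("stitching is idempotent, disjoint, and score-conserving", {
  withr::local_seed(9)
  for (rep in 1:50) {
    p <- random_peak_set(sample(1:60, 1))
    d <- sample(0:800, 1)
    r <- stitch_peaks(p, d)
    expect_equal(sum(r$score), sum(p$score))
    expect_equal(sum(r$n_members), nrow(p))
    # inter-region gaps exceed the stitch distance
    for (chr in unique(r$chrom)) {
      rc <- r[r$chrom == chr, , drop = FALSE]
      if (nrow(rc) > 1) {
        expect_true(all(rc$start[-1] - rc$end[-nrow(rc)] > d))
      }
    }
    # idempotence: restitching the regions changes nothing
    r2 <- stitch_peaks(
      peaks_df(r$chrom, r$start, r$end, name = r$name, score = r$score), d)
    expect_equal(r2[, c("chrom", "start", "end", "score")],
                 r[, c("chrom", "start", "end", "score")])
  }
})

test_that("build_rank_curve normalizes to the unit square", {
  r <- stitch_peaks(peaks_df("chr1", c(0, 1000), c(100, 1100),
                             score = c(2, 4)), 10)
  c1 <- build_rank_curve(r)
  expect_equal(c1$normalized_y, c(0.5, 1))
  expect_equal(c1$normalized_x, c(0, 1))

  # all equal scores: y identically 1
  re <- stitch_peaks(peaks_df("chr1", seq(0, 4000, 1000),
                              seq(100, 4100, 1000), score = 3), 10)
  expect_true(all(build_rank_curve(re)$normalized_y == 1))

  # single region: x = 0, y = 1
  r1 <- build_rank_curve(r[1, ])
  expect_equal(r1$normalized_x, 0)
  expect_equal(r1$normalized_y, 1)

  r0 <- r; r0$score <- 0
  expect_error(build_rank_curve(r0), "degenerate",
               class = "pf_domain_error")
})

# helper: regions spaced far apart with given scores
spaced_regions <- function(scores) {
  n <- length(scores)
  build_rank_curve(stitch_peaks(
    peaks_df("chr1", seq_len(n) * 10000, seq_len(n) * 10000 + 100,
             score = scores), 100))
}

test_that("call_clusters reproduces the canonical outcomes", {
  flat <- spaced_regions(rep(5, 10))
  res <- call_clusters(flat)
  expect_equal(sum(res$regions$is_cluster), 0L)
  expect_true(is.na(res$cutoff_score))

  one <- call_clusters(spaced_regions(c(rep(1, 99), 1000)))
  expect_equal(sum(one$regions$is_cluster), 1L)
  expect_equal(one$regions$score[one$regions$is_cluster], 1000)
  expect_equal(one$cutoff_score, 1)

  two <- call_clusters(spaced_regions(c(rep(1, 98), 900, 1000)))
  expect_equal(sum(two$regions$is_cluster), 2L)
  expect_setequal(two$regions$score[two$regions$is_cluster], c(900, 1000))

  # below min_regions: no clusters
  tiny <- call_clusters(spaced_regions(c(1, 100)))
  expect_equal(sum(tiny$regions$is_cluster), 0L)
  expect_true(is.na(tiny$cutoff_score))
})

test_that("cutoff equals the exhaustive slope-scan oracle", {
  withr::local_seed(31)
  for (rep in 1:100) {
    n <- sample(3:1000, 1)
    scores <- round(stats::rlnorm(n, 1, sample(c(0.3, 0.8, 1.5), 1)), 4)
    curve <- spaced_regions(scores)
    thr <- sample(c(0.5, 1, 2), 1)
    res <- call_clusters(curve, cluster_params(slope_threshold = thr))
    idx <- oracle_cutoff_index(curve$normalized_x, curve$normalized_y, thr)
    if (is.na(idx)) {
      expect_true(is.na(res$cutoff_score))
      expect_equal(sum(res$regions$is_cluster), 0L)
    } else {
      expect_equal(res$cutoff_score, curve$score[idx])
      expect_equal(res$regions$is_cluster,
                   curve$score > curve$score[idx])
    }
  }
})

test_that("cluster calls are scale-invariant and monotone in threshold", {
  withr::local_seed(13)
  for (rep in 1:30) {
    scores <- round(stats::rlnorm(sample(5:200, 1), 1, 1), 4)
    base <- call_clusters(spaced_regions(scores))
    scaled <- call_clusters(spaced_regions(scores * 37.5))
    expect_equal(scaled$regions$is_cluster, base$regions$is_cluster)
    higher <- call_clusters(spaced_regions(scores),
                            cluster_params(slope_threshold = 2))
    expect_lte(sum(higher$regions$is_cluster),
               sum(base$regions$is_cluster))
  }
})

test_that("convex curves cut within one rank of argmax(x - y)", {
  for (p in c(2, 3, 5)) {
    n <- 500
    x <- (seq_len(n) - 1) / (n - 1)
    scores <- x^p * 1000 + 1e-6
    curve <- spaced_regions(scores)
    res <- call_clusters(curve)
    cut_rank <- which(curve$score == res$cutoff_score)[1]
    tangent <- which.max(curve$normalized_x - curve$normalized_y)
    expect_lte(abs(cut_rank - tangent), 1)
  }
})
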