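deg_stats_df <- function(total, lfc = 0, p = 0.5) {
  n <- length(total)
  data.frame(gene_id = paste0("g", seq_len(n)), total_count = total,
             log2fc = rep_len(lfc, n), pvalue = rep_len(p, n),
             stringsAsFactors = FALSE)
}

test_that("filter_low_counts uses an inclusive threshold", {
  s <- deg_stats_df(c(10, 9, 0, 25))
  res <- filter_low_counts(s)
  expect_equal(res$kept$gene_id, c("g1", "g4"))
  expect_equal(res$filtered$gene_id, c("g2", "g3"))
  expect_equal(nrow(filter_low_counts(s, deg_params(min_total_count = 0))$filtered),
               0L)
  empty <- filter_low_counts(s[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$filtered), 0L)
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "pf_domain_error")

  withr::local_seed(55)
  for (rep in 1:1000) {
    n <- sample(c(1:60, 100, 250, 500), 1)  # sizes up to 500, mostly small
    p <- round(runif(n), 4)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))  # >= up to floating-point rounding
    # matches the reference implementation too
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    # permutation equivariance
    perm <- sample(n)
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("call_degs applies prefilter -> BH -> strict thresholds", {
  # log2fc exactly 1.0 is NOT a DEG (strict bound)
  s <- deg_stats_df(c(100, 100), lfc = c(1.0, 1.2), p = c(1e-6, 1e-6))
  calls <- call_degs(s)
  expect_equal(calls$status, c("not_significant", "up"))

  # filtered genes get no padj and do not influence BH for the rest
  s2 <- deg_stats_df(c(100, 100, 3, 100, 100), lfc = 2,
                     p = c(0.01, 0.02, 0.001, 0.03, 0.04))
  calls2 <- call_degs(s2)
  expect_equal(calls2$status[3], "filtered")
  expect_true(is.na(calls2$padj[3]))
  expect_equal(calls2$padj[-3], bh_adjust(s2$pvalue[-3]))
  # including the filtered gene would have changed the adjustment
  expect_false(isTRUE(all.equal(bh_adjust(s2$pvalue)[-3],
                                calls2$padj[-3])))

  # up/down are disjoint and order-invariant
  withr::local_seed(8)
  s3 <- deg_stats_df(sample(0:500, 300, replace = TRUE),
                     lfc = rnorm(300, 0, 2), p = runif(300)^2)
  c3 <- call_degs(s3)
  expect_equal(length(intersect(c3$gene_id[c3$status == "up"],
                                c3$gene_id[c3$status == "down"])), 0L)
  perm <- sample(300)
  c3p <- call_degs(s3[perm, ])
  expect_equal(table(c3p$status), table(c3$status))
  expect_equal(c3p$status, c3$status[perm])
})

test_that("planted simulation keeps empirical FDR under control", {
  withr::local_seed(90)
  fdrs <- replicate(100, {
    n <- 200; n_true <- 20
    is_true <- seq_len(n) <= n_true
    s <- data.frame(
      gene_id = paste0("g", seq_len(n)),
      total_count = 100,
      log2fc = ifelse(is_true, 2, rnorm(n, 0, 0.25)),
      pvalue = ifelse(is_true, rbeta(n, 0.1, 1), runif(n)),
      stringsAsFactors = FALSE)
    calls <- call_degs(s)
    up <- calls$status == "up"
    if (!any(up)) 0 else sum(up & !is_true) / sum(up)
  })
  expect_lte(mean(fdrs), 0.10)
})

test_that("pure-null call rate stays below the nominal level", {
  withr::local_seed(123)
  rate <- replicate(200, {
    s <- data.frame(gene_id = paste0("g", 1:1000), total_count = 50,
                    log2fc = rnorm(1000, 0, 2), pvalue = runif(1000),
                    stringsAsFactors = FALSE)
    calls <- call_degs(s)
    mean(calls$status %in% c("up", "down"))
  })
  expect_lte(mean(rate), 0.05 * 1.5)  # stochastic tolerance +-50%
})

test_that("venn_counts enumerates exclusive regions", {
  v <- venn_counts(list(A = c("a", "b"), B = c("b", "c"), C = "c"))
  expect_equal(v[["A"]], 1L)
  expect_equal(v[["A&B"]], 1L)
  expect_equal(v[["B&C"]], 1L)
  expect_equal(sum(v), 3L)  # |union|
  expect_equal(length(v), 7L)
  expect_equal(sum(v[c("B", "A&B", "B&C", "A&B&C")]), 2L)  # |B|

  d <- venn_counts(list(X = "x", Y = "y"))
  expect_equal(unname(d[c("X", "Y", "X&Y")]), c(1L, 1L, 0L))
  ident <- venn_counts(list(A = c("u", "v"), B = c("u", "v")))
  expect_equal(unname(ident[c("A", "B", "A&B")]), c(0L, 0L, 2L))
  expect_error(venn_counts(list(a = "x")), class = "pf_domain_error")
  expect_error(venn_counts(setNames(rep(list("x"), 6), letters[1:6])),
               class = "pf_domain_error")

  # region totals reconstruct every input set cardinality
  withr::local_seed(66)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    sets <- setNames(lapply(seq_len(k), function(i) {
      unique(sample(letters, sample(0:15, 1), replace = TRUE))
    }), LETTERS[seq_len(k)])
    v <- venn_counts(sets)
    for (nm in names(sets)) {
      containing <- vapply(strsplit(names(v), "&", fixed = TRUE),
                           function(s) nm %in% s, TRUE)
      expect_equal(sum(v[containing]), length(sets[[nm]]))
    }
    expect_equal(sum(v), length(unique(unlist(sets))))
  }
})

test_that("bona_fide_targets returns intersection and bound fraction", {
  res <- bona_fide_targets(paste0("g", 1:6), c("g1", "g2", "x"))
  expect_equal(res$targets, c("g1", "g2"))
  expect_equal(res$fraction_bound, 1 / 3)
  expect_equal(bona_fide_targets(c("a", "b"), c("a", "b", "c"))$fraction_bound,
               1)
  expect_equal(bona_fide_targets(character(0), "a")$fraction_bound, 0)
  expect_equal(bona_fide_targets(c("a"), character(0))$fraction_bound, 0)
})

test_that("DEG tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  s <- deg_stats_df(c(5, 500), lfc = c(-2.5, 3.25), p = c(1e-8, 0.5))
  write_deg_table(s, path)
  expect_equal(read_deg_stats(path), s)
  writeLines("gene_id\ttotal\tlfc", path)
  expect_error(read_deg_stats(path), "header", class = "pf_format_error")
})
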