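test_that("read_fasta parses, uppercases, validates", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 descriptive text", "acgt", ">chr2", "NNAC", "GT"), path)
  fa <- read_fasta(path)
  expect_identical(fa, c(chr1 = "ACGT", chr2 = "NNACGT"))

  writeLines(c(">chr1", "ACGT", ">chr1", "TTTT"), path)
  expect_error(read_fasta(path), "duplicate", class = "pf_format_error")

  writeLines(c(">chr1", "ACGX"), path)
  err <- tryCatch(read_fasta(path), condition = identity)
  expect_s3_class(err, "pf_format_error")
  expect_match(conditionMessage(err), "offset 3")
})

test_that("read_bed maps columns, defaults, and rejects bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t7.5\t.", "chr2\t0\t50"), path)
  p <- read_bed(path)
  expect_equal(p$start, c(100, 0))
  expect_equal(p$name, c("p1", "peak_2"))
  expect_equal(p$score, c(7.5, 0))
  expect_equal(p$strand, c(".", "."))

  writeLines("chr1\t200\t100", path)
  err <- tryCatch(read_bed(path), condition = identity)
  expect_s3_class(err, "pf_format_error")
  expect_match(conditionMessage(err), "line 1")

  writeLines("chr1\t1a0\t200", path)
  expect_error(read_bed(path), "non-integer", class = "pf_format_error")

  writeLines("chr1\t100\t200", path)
  expect_error(read_bed(path, min_cols = 6L), "columns",
               class = "pf_format_error")

  # duplicate names are suffixed to uniqueness
  writeLines(c("chr1\t0\t10\tsame", "chr1\t20\t30\tsame"), path)
  expect_false(anyDuplicated(read_bed(path)$name) > 0)
})

test_that("BED round-trip identity holds on randomized peak sets", {
  withr::local_seed(42)
  path <- withr::local_tempfile(fileext = ".bed")
  for (rep in 1:100) {
    p <- random_peak_set(sample(0:40, 1))
    write_bed(p, path)
    back <- read_bed(path)
    rownames(p) <- rownames(back) <- NULL
    expect_equal(back, p)
  }
  # empty set -> empty file, no header
  write_bed(p[0, ], path)
  expect_identical(readLines(path), character(0))
})

test_that("write_bed appends extra columns after column 6", {
  path <- withr::local_tempfile(fileext = ".bed")
  p <- peaks_df("chr1", c(0, 100), c(50, 160))
  write_bed(p, path, extra_columns = list(category = c("a", "b")))
  got <- strsplit(readLines(path), "\t")
  expect_true(all(lengths(got) == 7L))
  expect_equal(vapply(got, `[[`, "", 7L), c("a", "b"))
})

test_that("gene table round-trips and enforces invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  g <- rbind(
    gene_df("gplus", "chr1", "+", 1000, 3000, 1100, 2900,
            exon_sizes = "500,800", exon_starts = "0,1200"),
    gene_df("gminus", "chr1", "-", 5000, 8000),
    gene_df("gnc", "chr2", "+", 10, 500))
  write_gene_table(g, path)
  back <- read_gene_table(path)
  expect_equal(back$gene_id, g$gene_id)
  expect_equal(back$cds_start, g$cds_start)
  expect_equal(gene_tss(back), c(1000, 7999, 10))

  bad <- gene_df("bad", "chr1", "+", 0, 100,
                 exon_sizes = "200", exon_starts = "0")
  write_gene_table(bad, path)
  err <- tryCatch(read_gene_table(path), condition = identity)
  expect_s3_class(err, "pf_format_error")
  expect_match(conditionMessage(err), "bad")
})

test_that("interval_gap is symmetric, 0 iff overlapping/abutting", {
  a <- genomic_interval("chr1", 100, 200)
  expect_equal(interval_gap(a, genomic_interval("chr1", 150, 300)), 0)
  expect_equal(interval_gap(a, genomic_interval("chr1", 200, 300)), 0)
  expect_equal(interval_gap(a, genomic_interval("chr1", 700, 800)), 500)
  expect_identical(interval_gap(a, genomic_interval("chr2", 100, 200)), Inf)
  withr::local_seed(11)
  for (i in 1:200) {
    s1 <- sample(1000, 1); s2 <- sample(1000, 1)
    b1 <- genomic_interval("chr1", s1, s1 + sample(100, 1))
    b2 <- genomic_interval("chr1", s2, s2 + sample(100, 1))
    expect_identical(interval_gap(b1, b2), interval_gap(b2, b1))
    overlap_or_abut <- b1$start <= b2$end && b2$start <= b1$end
    expect_identical(interval_gap(b1, b2) == 0, overlap_or_abut)
  }
})

test_that("score_peaks_from_coverage matches per-base oracle and is additive", {
  cov1 <- data.frame(chrom = "chr1", start = 0, end = 10, value = 2)
  p <- peaks_df("chr1", 0, 10)
  expect_equal(score_peaks_from_coverage(p, cov1)$score, 20)
  # splitting a step into contiguous halves leaves the score unchanged
  cov2 <- data.frame(chrom = "chr1", start = c(0, 4), end = c(4, 10),
                     value = c(2, 2))
  expect_equal(score_peaks_from_coverage(p, cov2)$score, 20)
  # no coverage -> 0
  expect_equal(score_peaks_from_coverage(peaks_df("chr9", 5, 25), cov1)$score, 0)
  # overlapping steps are a format error
  bad <- data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15),
                    value = c(1, 1))
  expect_error(score_peaks_from_coverage(p, bad), "overlapping",
               class = "pf_format_error")

  withr::local_seed(5)
  for (rep in 1:20) {
    ns <- sample(1:8, 1)
    bounds <- sort(sample(0:400, ns + 1))
    bounds <- bounds[!duplicated(bounds)]
    if (length(bounds) < 2) next
    cov <- data.frame(chrom = "chr1", start = bounds[-length(bounds)],
                      end = bounds[-1],
                      value = round(runif(length(bounds) - 1, 0, 5), 2))
    cov <- cov[sample(nrow(cov), sample(nrow(cov), 1)), , drop = FALSE]
    s <- sample(0:380, 1)
    pk <- peaks_df("chr1", s, s + sample(5:60, 1))
    expect_equal(score_peaks_from_coverage(pk, cov)$score,
                 oracle_cov_score(pk[1, ], cov))
  }
})

test_that("bedGraph round-trips", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  cov <- data.frame(chrom = c("chr1", "chr1"), start = c(0, 10),
                    end = c(10, 25), value = c(1.5, 0.25))
  write_bedgraph(cov, path)
  expect_equal(read_bedgraph(path), cov)
})
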