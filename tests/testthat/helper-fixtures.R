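# Builders and independent oracles shared across the suite. Oracles are
# deliberately naive (per-window, per-base, per-rank loops) and share no
# code with the implementation they check.

peaks_df <- function(chrom, start, end, name = NULL, score = 0,
                     strand = ".") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             name = if (is.null(name)) sprintf("p%d", seq_len(n)) else name,
             score = rep_len(score, n), strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

gene_df <- function(gene_id, chrom, strand, tx_start, tx_end,
                    cds_start = NA, cds_end = NA,
                    exon_sizes = NULL, exon_starts = NULL) {
  if (is.null(exon_sizes)) {
    exon_sizes <- as.character(tx_end - tx_start)
    exon_starts <- "0"
  }
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tx_start = tx_start, tx_end = tx_end,
             cds_start = cds_start, cds_end = cds_end,
             exon_sizes = exon_sizes, exon_starts = exon_starts,
             stringsAsFactors = FALSE)
}

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

IUPAC_TAB <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                H = "D", V = "B", N = "N")

# brute-force sliding-window matcher; returns 0-based window starts
oracle_scan_starts <- function(sequence, pattern) {
  seq_chars <- strsplit(toupper(sequence), "")[[1L]]
  pat <- strsplit(toupper(pattern), "")[[1L]]
  L <- length(pat)
  n <- length(seq_chars)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!seq_chars[s + j] %in% IUPAC_TAB[[pat[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

oracle_revcomp <- function(pattern) {
  paste(rev(IUPAC_COMP[strsplit(toupper(pattern), "")[[1L]]]),
        collapse = "")
}

# both-strand oracle hit table matching scan_sequence's contract
oracle_scan <- function(sequence, pattern, strands = "both") {
  fwd <- oracle_scan_starts(sequence, pattern)
  out <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (strands == "both") {
    rev_ <- oracle_scan_starts(sequence, oracle_revcomp(pattern))
    out <- rbind(out, data.frame(start = rev_,
                                 strand = rep("-", length(rev_))))
  }
  out[order(out$start, out$strand, method = "radix"), , drop = FALSE]
}

# brute-force BH step-up by its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# per-base coverage integral
oracle_cov_score <- function(peak, coverage) {
  total <- 0
  for (b in seq(peak$start, peak$end - 1)) {
    row <- which(coverage$chrom == peak$chrom & coverage$start <= b &
                   b < coverage$end)
    if (length(row)) total <- total + coverage$value[row[1L]]
  }
  total
}

# exhaustive slope scan: first rank with central-difference slope > thr
oracle_cutoff_index <- function(x, y, thr = 1) {
  n <- length(x)
  for (i in seq_len(n)) {
    s <- if (i == 1L) (y[2L] - y[1L]) / (x[2L] - x[1L])
    else if (i == n) (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    else (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
    if (s > thr) return(i)
  }
  NA_integer_
}

# per-gene, per-feature brute-force midpoint classifier mirroring the
# documented rules (priority, strand-aware windows, tie-breaks)
oracle_classify_mid <- function(mid, genes, params) {
  best <- list(rank = 99L, absd = Inf, gene = NA_character_,
               d = NA_real_)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- gene_exons(g)
    tss <- if (g$strand == "+") g$tx_start else g$tx_end - 1
    d <- if (g$strand == "+") mid - tss else tss - mid
    in_any <- function(s, e) any(s <= mid & mid < e)
    pw <- if (g$strand == "+") {
      c(max(0, tss - params$promoter_upstream_bp),
        tss + params$promoter_downstream_bp)
    } else {
      c(max(0, tss - params$promoter_downstream_bp + 1),
        tss + params$promoter_upstream_bp + 1)
    }
    rank <- NA_integer_
    if (in_any(pw[1L], pw[2L])) {
      rank <- 1L
    } else if (!is.na(g$cds_start) && (
      if (g$strand == "+") in_any(pmax(ex$start, g$cds_end),
                                  pmin(ex$end, g$tx_end))
      else in_any(pmax(ex$start, g$tx_start), pmin(ex$end, g$cds_start)))) {
      rank <- 2L
    } else if (in_any(ex$start, ex$end)) {
      rank <- 3L
    } else if (g$tx_start <= mid && mid < g$tx_end) {
      rank <- 4L
    } else if (d < 0 && -d <= params$distal_max_bp) {
      rank <- 5L
    }
    if (is.na(rank) || abs(d) > params$link_max_bp) next
    if (rank < best$rank ||
        (rank == best$rank && (abs(d) < best$absd ||
          (abs(d) == best$absd && (is.na(best$gene) ||
                                   g$gene_id < best$gene))))) {
      best <- list(rank = rank, absd = abs(d), gene = g$gene_id, d = d)
    }
  }
  cats <- c("promoter", "three_prime_utr", "exon", "intron", "distal")
  if (best$rank > 5L) {
    list(category = "intergenic", gene = NA_character_, d = NA_real_)
  } else {
    list(category = cats[best$rank], gene = best$gene, d = best$d)
  }
}

random_peak_set <- function(n, chroms = c("chr1", "chr2"),
                            max_pos = 10000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  peaks_df(sample(chroms, n, replace = TRUE), start,
           start + sample(10:500, n, replace = TRUE),
           name = sprintf("rp%d", seq_len(n)),
           score = round(runif(n, 0, 100), 3),
           strand = sample(c("+", "-", "."), n, replace = TRUE))
}

small_fixture_config <- function(seed = 7, ...) {
  fixture_config(seed = seed, genome_bp = 150000, n_genes = 20,
                 n_tf_peaks = 150, n_planted_clusters = 3,
                 cluster_member_range = c(3, 5), n_deg_up = 12, ...)
}
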