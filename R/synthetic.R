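# Deterministic synthetic-fixture generator. It emits the complete desk-
# scale input bundle of the downstream pipeline -- genome FASTA, gene
# models, TF and H3K27ac peak BEDs, coverage bedGraph, per-gene DE
# statistics -- plus a ground-truth manifest (truth.json) for recovery
# tests. Decoy peaks violate exactly one high-confidence condition each,
# so filter errors are attributable. Background sequence is i.i.d. uniform
# over ACGT; accidental motif occurrences are censused, not suppressed.

#' Configuration of the synthetic fixture generator
#'
#' Defaults state a desk-scale world that mirrors the shape of a real
#' TF/H3K27ac ChIP experiment: ~6,000 TF peaks of which 73% are true
#' high-confidence (motif present and an H3K27ac peak within the pass
#' offset), planted score-boosted peak groups standing in for enhancer
#' clusters, and a DE table in which one third of the true induced genes
#' are TF-bound.
#'
#' @param seed Integer seed; the bundle is byte-identical given a seed.
#' @param genome_bp Genome length (single chromosome "chr1").
#' @param n_genes Number of gene models.
#' @param n_tf_peaks Number of TF peaks.
#' @param frac_high_confidence Fraction of TF peaks that are true
#'   high-confidence; the rest are decoys, half missing the motif, half
#'   with the H3K27ac mark at the fail offset.
#' @param n_planted_clusters Number of planted enhancer clusters.
#' @param cluster_member_range Length-2 integer vector: min/max peaks per
#'   planted cluster.
#' @param cluster_score_boost Multiplier applied to cluster member scores.
#' @param k27_offset_pass_bp Maximum H3K27ac gap planted for passing
#'   peaks; must be <= 500.
#' @param k27_offset_fail_bp H3K27ac gap planted for failing decoys; must
#'   be > 500.
#' @param n_deg_up Number of true up-regulated genes in the DE table.
#' @param frac_deg_bound Fraction of true DEGs assigned to bound genes.
#' @param score_body Length-2 numeric vector (meanlog, sdlog) of the
#'   log-normal peak-score body.
#' @param stitch_distance_bp Stitch scale the fixture geometry is built
#'   around: gaps inside planted clusters stay below it, all other
#'   inter-peak gaps stay above it. Default 500 (desk scale).
#' @return List of class \code{fixture_config}.
#' @export
fixture_config <- function(seed = 1L,
                           genome_bp = 5e6,
                           n_genes = 400L,
                           n_tf_peaks = 6000L,
                           frac_high_confidence = 0.73,
                           n_planted_clusters = 25L,
                           cluster_member_range = c(3L, 8L),
                           cluster_score_boost = 20,
                           k27_offset_pass_bp = 200L,
                           k27_offset_fail_bp = 2000L,
                           n_deg_up = 60L,
                           frac_deg_bound = 0.33,
                           score_body = c(meanlog = 1.0, sdlog = 0.6),
                           stitch_distance_bp = 500L) {
  cfg <- list(seed = as.integer(seed), genome_bp = genome_bp,
              n_genes = as.integer(n_genes),
              n_tf_peaks = as.integer(n_tf_peaks),
              frac_high_confidence = frac_high_confidence,
              n_planted_clusters = as.integer(n_planted_clusters),
              cluster_member_range = as.integer(cluster_member_range),
              cluster_score_boost = cluster_score_boost,
              k27_offset_pass_bp = as.integer(k27_offset_pass_bp),
              k27_offset_fail_bp = as.integer(k27_offset_fail_bp),
              n_deg_up = as.integer(n_deg_up),
              frac_deg_bound = frac_deg_bound,
              score_body = score_body,
              stitch_distance_bp = as.integer(stitch_distance_bp))
  if (cfg$frac_high_confidence < 0 || cfg$frac_high_confidence > 1 ||
      cfg$frac_deg_bound < 0 || cfg$frac_deg_bound > 1) {
    pf_config_error("fractions must lie in [0, 1]")
  }
  if (any(c(cfg$genome_bp, cfg$n_genes, cfg$n_tf_peaks,
            cfg$n_planted_clusters, cfg$n_deg_up) < 0)) {
    pf_config_error("counts must be >= 0")
  }
  if (!(cfg$k27_offset_pass_bp <= 500 && 500 < cfg$k27_offset_fail_bp)) {
    pf_config_error("need k27_offset_pass_bp <= 500 < k27_offset_fail_bp")
  }
  if (length(cfg$cluster_member_range) != 2L ||
      cfg$cluster_member_range[1L] < 1L ||
      diff(cfg$cluster_member_range) < 0L) {
    pf_config_error("cluster_member_range must be an increasing pair >= 1")
  }
  structure(cfg, class = "fixture_config")
}

# m slot indices out of n with pairwise spacing >= gap, uniform at random
.spaced_sample <- function(n, m, gap) {
  if (m == 0L) return(integer(0))
  avail <- n - (m - 1L) * (gap - 1L)
  if (avail < m) {
    pf_capacity_error(sprintf(
      "cannot place %d spaced features in %d slots", m, n))
  }
  sort(sample.int(avail, m)) + (gap - 1L) * (seq_len(m) - 1L)
}

.runif_int <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1L))

#' Generate a complete synthetic fixture bundle
#'
#' Writes genome.fa, genes.tsv, tf_peaks.bed, k27_peaks.bed,
#' coverage.bedGraph, deg_stats.tsv and truth.json into \code{out_dir}.
#' The bundle is fully deterministic given \code{config$seed}
#' (byte-identical across runs).
#'
#' Guarantees of the planted world: every true high-confidence peak
#' contains >= 1 planted GAS window and has an H3K27ac peak at gap <=
#' \code{k27_offset_pass_bp}; motif-missing decoys are scrubbed of all GAS
#' windows inside the peak but keep a passing H3K27ac mark; H3K27ac-fail
#' decoys keep a planted motif but their mark sits at
#' \code{k27_offset_fail_bp}, with the layout spaced so no other mark
#' rescues them. Planted clusters are runs of true peaks whose internal
#' gaps stay below \code{stitch_distance_bp} while all other gaps exceed
#' it, with member scores boosted by \code{cluster_score_boost}.
#'
#' @param config \code{\link{fixture_config}}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the emitted file paths and the truth
#'   manifest.
#' @export
generate_fixture <- function(config = fixture_config(), out_dir) {
  if (!inherits(config, "fixture_config")) {
    pf_config_error("config must be a fixture_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_tf_peaks
  stitch <- config$stitch_distance_bp

  ## ---- peak slot labels -------------------------------------------------
  n_true <- round(config$frac_high_confidence * n)
  n_decoy <- n - n_true
  n_k27fail <- n_decoy %/% 2L
  n_motifless <- n_decoy - n_k27fail
  label <- rep("true_hc", n)
  # H3K27ac-fail decoys are spaced >= 5 slots apart so one decoy's
  # far-offset mark can never land within the pass window of another
  k27fail_slots <- .spaced_sample(n, n_k27fail, 5L)
  label[k27fail_slots] <- "decoy_k27"

  ## ---- planted cluster runs over free consecutive slots ----------------
  cluster_id <- rep(NA_integer_, n)
  sizes <- .runif_int(config$n_planted_clusters,
                      config$cluster_member_range[1L],
                      config$cluster_member_range[2L])
  taken <- label != "true_hc"
  starts <- sample.int(n)
  ci <- 0L
  for (s in starts) {
    if (ci >= config$n_planted_clusters) break
    k <- sizes[ci + 1L]
    if (s + k - 1L > n) next
    idx <- s:(s + k - 1L)
    if (any(taken[idx]) || any(!is.na(cluster_id[idx]))) next
    ci <- ci + 1L
    cluster_id[idx] <- ci
  }
  if (ci < config$n_planted_clusters) {
    pf_capacity_error(sprintf(
      "could only place %d of %d planted clusters", ci,
      config$n_planted_clusters))
  }
  # motif-missing decoys: any remaining non-cluster true slot
  free <- which(label == "true_hc" & is.na(cluster_id))
  if (length(free) < n_motifless) {
    pf_capacity_error("not enough free slots for motif-missing decoys")
  }
  label[sample(free, n_motifless)] <- "decoy_motif"

  ## ---- geometry ---------------------------------------------------------
  width <- .runif_int(n, 120L, 180L)
  same_cluster <- !is.na(cluster_id[-1L]) & !is.na(cluster_id[-n]) &
    cluster_id[-1L] == cluster_id[-n]
  in_cluster_gap <- c(FALSE, same_cluster)
  gap <- integer(n)  # gap BEFORE each peak
  gap[1L] <- 1000L
  for (i in seq_len(n)[-1L]) {
    gap[i] <- if (in_cluster_gap[i]) {
      .runif_int(1L, 100L, max(101L, stitch - 200L))
    } else if (label[i] == "decoy_k27") {
      # room for the previous peak's mark plus the pass window
      .runif_int(1L, stitch + 400L + config$k27_offset_pass_bp,
                 stitch + 460L + config$k27_offset_pass_bp)
    } else {
      .runif_int(1L, stitch + 20L, stitch + 120L)
    }
  }
  start <- cumsum(gap) + cumsum(c(0L, width[-n]))
  end <- start + width
  tail_margin <- config$k27_offset_fail_bp + 700L
  if (n && end[n] + tail_margin > config$genome_bp) {
    pf_capacity_error(sprintf(
      "genome of %d bp cannot hold %d peaks (need %d bp)",
      config$genome_bp, n, end[n] + tail_margin))
  }

  ## ---- genome with planted / scrubbed motifs ---------------------------
  base <- c("A", "C", "G", "T")
  genome_chars <- sample(base, config$genome_bp, replace = TRUE)
  motif_pos <- rep(NA_real_, n)
  plant <- which(label %in% c("true_hc", "decoy_k27"))
  for (i in plant) {
    pos <- start[i] + .runif_int(1L, 0L, width[i] - 9L)  # 0-based
    genome_chars[(pos + 1L):(pos + 9L)] <-
      c("T", "T", "C", sample(base, 3L, replace = TRUE), "G", "A", "A")
    motif_pos[i] <- pos
  }
  gas <- gas_motif()
  for (i in which(label == "decoy_motif")) {
    # scrub every GAS window (palindrome: forward scan sees all windows)
    for (iter in 1:50) {
      seq_i <- paste(genome_chars[(start[i] + 1L):end[i]], collapse = "")
      h <- .scan_starts(seq_i, gas)
      if (!length(h)) break
      genome_chars[start[i] + h + 3L] <- "T"  # TTC -> TTT kills the core
    }
    if (length(.scan_starts(
      paste(genome_chars[(start[i] + 1L):end[i]], collapse = ""), gas))) {
      pf_error("motif scrub failed to converge", "pf_internal_error")
    }
  }
  genome <- c(chr1 = paste(genome_chars, collapse = ""))

  ## ---- scores and TF/K27 peak tables ------------------------------------
  score <- stats::rlnorm(n, config$score_body[[1L]], config$score_body[[2L]])
  score[!is.na(cluster_id)] <- score[!is.na(cluster_id)] *
    config$cluster_score_boost
  score <- round(score, 4L)
  tf <- data.frame(chrom = "chr1", start = start, end = end,
                   name = sprintf("tfpeak_%05d", seq_len(n)),
                   score = score, strand = ".", stringsAsFactors = FALSE)
  k27_w <- .runif_int(n, 100L, 180L)
  k27_gap <- ifelse(label == "decoy_k27", config$k27_offset_fail_bp,
                    .runif_int(n, 0L, config$k27_offset_pass_bp))
  k27 <- data.frame(chrom = "chr1", start = end + k27_gap,
                    end = end + k27_gap + k27_w,
                    name = sprintf("k27_%05d", seq_len(n)),
                    score = round(stats::rlnorm(n, 1, 0.5), 4L),
                    strand = ".", stringsAsFactors = FALSE)

  ## ---- gene models -------------------------------------------------------
  genes <- .generate_genes(config)

  ## ---- DE statistics with planted bound/unbound DEGs --------------------
  true_peaks <- tf[label == "true_hc", , drop = FALSE]
  ann <- classify_peaks(true_peaks, genes)
  bound_genes <- sort(unique(stats::na.omit(ann$target_gene)))
  deg <- .generate_deg(config, genes, bound_genes)

  ## ---- coverage: constant step per peak reproducing its score -----------
  coverage <- data.frame(chrom = "chr1", start = start, end = end,
                         value = round(score / width, 6L),
                         stringsAsFactors = FALSE)

  ## ---- truth manifest ----------------------------------------------------
  census <- background_motif_census(genome, gas,
                                    planted = motif_pos[!is.na(motif_pos)])
  truth <- list(
    config = unclass(config),
    peaks = list(name = tf$name, label = label,
                 cluster_id = cluster_id, planted_motif_pos = motif_pos),
    clusters = lapply(seq_len(ci), function(j) {
      list(cluster_id = j, members = tf$name[which(cluster_id == j)])
    }),
    bound_genes = bound_genes,
    genes = deg$truth,
    n_true_high_confidence = sum(label == "true_hc"),
    n_decoy_motif = sum(label == "decoy_motif"),
    n_decoy_k27 = sum(label == "decoy_k27"),
    background_motif_census = census,
    stitch_distance_bp = stitch)

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    genes = file.path(out_dir, "genes.tsv"),
    tf_peaks = file.path(out_dir, "tf_peaks.bed"),
    k27_peaks = file.path(out_dir, "k27_peaks.bed"),
    coverage = file.path(out_dir, "coverage.bedGraph"),
    deg_stats = file.path(out_dir, "deg_stats.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_fasta(genome, paths$genome)
  write_gene_table(genes, paths$genes)
  write_bed(tf, paths$tf_peaks)
  write_bed(k27, paths$k27_peaks)
  write_bedgraph(coverage, paths$coverage)
  write_deg_table(deg$stats, paths$deg_stats)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(list(paths = paths, truth = truth))
}

.generate_genes <- function(config) {
  ng <- config$n_genes
  if (!ng) return(.empty_genes())
  slot <- floor(config$genome_bp / ng)
  L_max <- slot - 2600L
  if (L_max < 1200L) {
    pf_capacity_error("genome too small for the requested gene count")
  }
  L_min <- min(3000L, floor(L_max * 0.8))
  g <- vector("list", ng)
  for (i in seq_len(ng)) {
    tx_start <- (i - 1L) * slot + .runif_int(1L, 0L, 2000L)
    L <- .runif_int(1L, L_min, min(9000L, L_max))
    ne <- .runif_int(1L, 2L, 4L)
    block <- L %/% ne
    e_len <- .runif_int(ne, 150L, min(400L, block - 120L))
    e_start <- (seq_len(ne) - 1L) * block
    e_start[1L] <- 0L
    e_start[ne] <- L - e_len[ne]  # transcript ends with an exon
    coding <- runif(1) < 0.85
    cds_start <- if (coding) tx_start + .runif_int(1L, 30L, 100L) else NA
    cds_end <- if (coding) tx_start + L - .runif_int(1L, 30L, 100L) else NA
    g[[i]] <- data.frame(
      gene_id = sprintf("gene_%04d", i), chrom = "chr1",
      strand = if (runif(1) < 0.5) "+" else "-",
      tx_start = tx_start, tx_end = tx_start + L,
      cds_start = cds_start, cds_end = cds_end,
      exon_sizes = paste(e_len, collapse = ","),
      exon_starts = paste(e_start, collapse = ","),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, g)
  validate_genes(genes, "synthetic genes")
  genes
}

.generate_deg <- function(config, genes, bound_genes) {
  n_up <- config$n_deg_up
  n_bound <- round(config$frac_deg_bound * n_up)
  if (length(bound_genes) < n_bound) {
    pf_capacity_error(sprintf(
      "only %d bound genes available, need %d planted bound DEGs",
      length(bound_genes), n_bound))
  }
  extra <- sprintf("xgene_%04d", seq_len(2L * max(config$n_genes, 1L)))
  universe <- c(genes$gene_id, extra)
  deg_bound <- sample(bound_genes, n_bound)
  deg_unbound <- sample(extra, n_up - n_bound)
  deg_ids <- c(deg_bound, deg_unbound)
  is_deg <- universe %in% deg_ids
  m <- length(universe)
  total <- integer(m); lfc <- numeric(m); p <- numeric(m)
  nn <- sum(!is_deg)
  low <- runif(nn) < 0.08  # a slice of genes below the count prefilter
  total[!is_deg] <- ifelse(low, .runif_int(nn, 0L, 9L),
                           10L + stats::rnbinom(nn, size = 2, mu = 290))
  lfc[!is_deg] <- stats::rnorm(nn, 0, 0.25)
  p[!is_deg] <- runif(nn)
  nd <- sum(is_deg)
  total[is_deg] <- 50L + stats::rnbinom(nd, size = 5, mu = 450)
  lfc[is_deg] <- stats::rnorm(nd, 2, 0.25)
  p[is_deg] <- stats::rbeta(nd, 0.1, 1)
  stats <- data.frame(gene_id = universe, total_count = total,
                      log2fc = round(lfc, 4L),
                      pvalue = signif(pmin(pmax(p, 1e-300), 1), 6L),
                      stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = universe, is_true_deg = is_deg,
                      direction = ifelse(is_deg, "up", "none"),
                      is_bound = universe %in% bound_genes,
                      stringsAsFactors = FALSE)
  list(stats = stats, truth = truth)
}

#' Census of motif windows outside planted positions
#'
#' Counts all unique motif windows in the genome (both strands; the two
#' strands of a palindromic consensus occupy the same window) whose start
#' is not among the planted positions. For an i.i.d. uniform background
#' the expected forward-strand rate of TTCNNNGAA is (1/4)^6 per window.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param pattern \code{motif_pattern}; default GAS.
#' @param planted Numeric vector of planted 0-based window starts (single
#'   chromosome), or a list named by chromosome.
#' @return Integer count of accidental (non-planted) windows.
#' @export
background_motif_census <- function(genome, pattern = gas_motif(),
                                    planted = numeric(0)) {
  if (!is.list(planted)) {
    planted <- setNames(list(planted), names(genome)[1L])
  }
  total <- 0L
  for (chr in names(genome)) {
    h <- scan_sequence(genome[[chr]], pattern, "both")
    w <- unique(h$start)
    total <- total + sum(!w %in% (planted[[chr]] %||% numeric(0)))
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a
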