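# Pipeline orchestration: simulate (optional) -> high-confidence filter ->
# enhancer clusters -> annotation -> DEG calling -> binding-expression
# integration, with a strict structured config and a machine-readable run
# report. Logging goes to standard error; the report and all stage outputs
# go to files, so stages stay shell-composable.

.PF_VERSION <- function() {
  as.character(utils::packageVersion("peakforge"))
}

.config_defaults <- function() {
  list(
    seed = 1L,
    simulate = NULL,
    inputs = list(genome = NULL, tf_peaks = NULL, k27_peaks = NULL,
                  genes = NULL, deg_stats = NULL, coverage = NULL),
    out_dir = NULL,
    confidence = list(window_bp = 500, motif = "TTCNNNGAA",
                      require_motif = TRUE),
    clusters = list(stitch_distance_bp = 12500, slope_threshold = 1,
                    min_regions = 3),
    annotation = list(promoter_upstream_bp = 1000,
                      promoter_downstream_bp = 100,
                      distal_max_bp = 50000, link_max_bp = 100000),
    deg = list(min_total_count = 10, lfc_threshold = 1,
               padj_threshold = 0.05),
    venn_lists = NULL)
}

# merge user values over defaults, strictly: unknown keys are errors
.merge_strict <- function(defaults, user, path, errors) {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown config key '%s'", here))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]]) &&
        !is.null(user[[key]])) {
      if (!is.list(user[[key]])) {
        errors$msgs <- c(errors$msgs,
                         sprintf("config key '%s' must be a table", here))
      } else {
        defaults[[key]] <- .merge_strict(defaults[[key]], user[[key]],
                                         here, errors)
      }
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' The config is a JSON object with keys \code{seed}, \code{simulate}
#' (fixture-generator overrides, or absent to consume existing inputs),
#' \code{inputs} (paths: genome, tf_peaks, k27_peaks, genes, deg_stats,
#' optional coverage), \code{out_dir}, and parameter tables
#' \code{confidence}, \code{clusters}, \code{annotation}, \code{deg},
#' plus optional \code{venn_lists} (name -> gene-list file, 2-5 entries).
#' Unknown keys are rejected; every error names the offending key path.
#'
#' @param path Path to a JSON config file, or an already-parsed list.
#' @return Normalized config list of class \code{pipeline_config}; on any
#'   problem a \code{pf_config_error} carrying all messages is raised.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) {
      pf_config_error(sprintf("config file not found: %s", path))
    }
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) {
               pf_config_error(sprintf("config not parseable as JSON: %s",
                                       conditionMessage(e)))
             })
  } else path
  errors <- new.env()
  errors$msgs <- character(0)
  # simulate is an open sub-table (fixture_config arguments), merged apart
  sim <- user$simulate
  user$simulate <- NULL
  cfg <- .merge_strict(.config_defaults(), user, "", errors)
  if (!is.null(sim)) {
    allowed <- names(formals(fixture_config))
    bad <- setdiff(names(sim), allowed)
    if (length(bad)) {
      errors$msgs <- c(errors$msgs, sprintf(
        "unknown config key 'simulate.%s'", bad))
    } else {
      cfg$simulate <- sim
    }
  }
  if (is.null(cfg$out_dir)) {
    errors$msgs <- c(errors$msgs, "missing required key 'out_dir'")
  }
  if (is.null(cfg$simulate)) {
    need <- c("genome", "tf_peaks", "k27_peaks", "genes", "deg_stats")
    for (key in need) {
      p <- cfg$inputs[[key]]
      if (is.null(p)) {
        errors$msgs <- c(errors$msgs,
                         sprintf("missing required key 'inputs.%s'", key))
      } else if (!file.exists(p)) {
        errors$msgs <- c(errors$msgs,
                         sprintf("inputs.%s: file not found: %s", key, p))
      }
    }
    if (!is.null(cfg$inputs$coverage) && !file.exists(cfg$inputs$coverage)) {
      errors$msgs <- c(errors$msgs, sprintf(
        "inputs.coverage: file not found: %s", cfg$inputs$coverage))
    }
  }
  check_num <- function(x, key, min = 0, strict = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
      (if (strict) x > min else x >= min)
    if (!ok) {
      errors$msgs <- c(errors$msgs, sprintf(
        "config key '%s' must be a number %s %s", key,
        if (strict) ">" else ">=", min))
    }
  }
  check_num(cfg$confidence$window_bp, "confidence.window_bp")
  check_num(cfg$clusters$stitch_distance_bp, "clusters.stitch_distance_bp")
  check_num(cfg$clusters$slope_threshold, "clusters.slope_threshold",
            strict = TRUE)
  check_num(cfg$annotation$promoter_upstream_bp,
            "annotation.promoter_upstream_bp")
  check_num(cfg$annotation$promoter_downstream_bp,
            "annotation.promoter_downstream_bp")
  check_num(cfg$annotation$distal_max_bp, "annotation.distal_max_bp")
  check_num(cfg$annotation$link_max_bp, "annotation.link_max_bp")
  check_num(cfg$deg$min_total_count, "deg.min_total_count")
  check_num(cfg$deg$lfc_threshold, "deg.lfc_threshold", strict = TRUE)
  check_num(cfg$deg$padj_threshold, "deg.padj_threshold", strict = TRUE)
  if (is.numeric(cfg$annotation$distal_max_bp) &&
      is.numeric(cfg$annotation$link_max_bp) &&
      cfg$annotation$distal_max_bp > cfg$annotation$link_max_bp) {
    errors$msgs <- c(errors$msgs,
                     "annotation.distal_max_bp must be <= link_max_bp")
  }
  if (!is.null(cfg$venn_lists)) {
    if (length(cfg$venn_lists) < 2L || length(cfg$venn_lists) > 5L ||
        is.null(names(cfg$venn_lists))) {
      errors$msgs <- c(errors$msgs,
                       "venn_lists must name 2 to 5 gene-list files")
    } else {
      for (nm in names(cfg$venn_lists)) {
        if (!file.exists(cfg$venn_lists[[nm]])) {
          errors$msgs <- c(errors$msgs, sprintf(
            "venn_lists.%s: file not found: %s", nm, cfg$venn_lists[[nm]]))
        }
      }
    }
  }
  if (length(errors$msgs)) {
    pf_config_error(paste(errors$msgs, collapse = "\n"))
  }
  structure(cfg, class = "pipeline_config")
}

.log <- function(fmt, ..., verbose = TRUE) {
  if (verbose) message(sprintf(paste0("[peakforge] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes, in dependency order: optional fixture simulation, coverage
#' scoring (when a coverage track is configured), the high-confidence peak
#' filter, peak stitching and enhancer-cluster calling on the
#' high-confidence set, genomic-category annotation, DEG calling, and
#' binding-expression integration. Every stage writes its table under
#' \code{out_dir}; a machine-readable report (JSON) summarizes counts at
#' every stage. Re-running on identical inputs reproduces the identical
#' report apart from the timestamp.
#'
#' @param config A \code{pipeline_config} (see \code{\link{validate_config}})
#'   or a path to a JSON config file.
#' @param verbose Log stage progress to standard error.
#' @return The run report, invisibly (also written to
#'   \code{out_dir/report.json}).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- config$inputs
  if (!is.null(config$simulate)) {
    .log("stage simulate: generating fixture", verbose = verbose)
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    fix_dir <- file.path(config$out_dir, "fixture")
    fx <- generate_fixture(do.call(fixture_config, sim_args), fix_dir)
    inputs <- list(genome = fx$paths$genome, tf_peaks = fx$paths$tf_peaks,
                   k27_peaks = fx$paths$k27_peaks, genes = fx$paths$genes,
                   deg_stats = fx$paths$deg_stats, coverage = NULL)
  }
  .log("stage load: reading inputs", verbose = verbose)
  genome <- read_fasta(inputs$genome)
  tf <- read_bed(inputs$tf_peaks, min_cols = 3L)
  k27 <- read_bed(inputs$k27_peaks, min_cols = 3L)
  genes <- read_gene_table(inputs$genes)
  stats <- read_deg_stats(inputs$deg_stats)
  if (!is.null(inputs$coverage)) {
    .log("stage score: scoring peaks from coverage", verbose = verbose)
    tf <- score_peaks_from_coverage(tf, read_bedgraph(inputs$coverage))
  }

  .log("stage confident-peaks: %d TF peaks", nrow(tf), verbose = verbose)
  cpar <- confidence_params(
    window_bp = config$confidence$window_bp,
    motif = motif_pattern(config$confidence$motif),
    require_motif = config$confidence$require_motif)
  conf <- filter_high_confidence(tf, k27, genome, cpar)
  write_bed(conf$passing, file.path(config$out_dir, "high_confidence.bed"))
  write_deg_table(conf$audit, file.path(config$out_dir,
                                        "confidence_audit.tsv"))

  .log("stage clusters: stitching %d peaks", nrow(conf$passing),
       verbose = verbose)
  kpar <- cluster_params(config$clusters$stitch_distance_bp,
                         config$clusters$slope_threshold,
                         config$clusters$min_regions)
  regions <- stitch_peaks(conf$passing, kpar$stitch_distance_bp)
  cl <- if (nrow(regions) && max(regions$score) > 0) {
    call_clusters(build_rank_curve(regions), kpar)
  } else {
    regions$is_cluster <- logical(nrow(regions))
    list(regions = regions, cutoff_score = NA_real_)
  }
  rc <- cl$regions
  write_deg_table(rc[, setdiff(names(rc), "members")],
                  file.path(config$out_dir, "rank_curve.tsv"))
  ro <- rc[order(rc$chrom, rc$start), , drop = FALSE]
  write_bed(data.frame(chrom = ro$chrom, start = ro$start, end = ro$end,
                       name = ro$name, score = ro$score, strand = ".",
                       stringsAsFactors = FALSE),
            file.path(config$out_dir, "stitched_regions.bed"),
            extra_columns = list(is_cluster = ifelse(ro$is_cluster, "1", "0")))

  .log("stage annotate: classifying peaks", verbose = verbose)
  apar <- annotation_params(config$annotation$promoter_upstream_bp,
                            config$annotation$promoter_downstream_bp,
                            config$annotation$distal_max_bp,
                            config$annotation$link_max_bp)
  ann <- classify_peaks(conf$passing, genes, apar)
  write_deg_table(ann, file.path(config$out_dir, "annotated_peaks.tsv"))
  dist <- category_distribution(ann)

  .log("stage deg: calling DEGs on %d genes", nrow(stats),
       verbose = verbose)
  dpar <- deg_params(config$deg$min_total_count, config$deg$lfc_threshold,
                     config$deg$padj_threshold)
  calls <- call_degs(stats, dpar)
  write_deg_table(calls, file.path(config$out_dir, "deg_calls.tsv"))

  .log("stage integrate: binding x expression", verbose = verbose)
  bound_genes <- sort(unique(stats::na.omit(ann$target_gene)))
  up_genes <- calls$gene_id[calls$status == "up"]
  down_genes <- calls$gene_id[calls$status == "down"]
  bona <- bona_fide_targets(up_genes, bound_genes)
  venn_sets <- if (!is.null(config$venn_lists)) {
    lapply(config$venn_lists, function(p) readLines(p, warn = FALSE))
  } else {
    list(deg_up = up_genes, bound = bound_genes)
  }
  venn <- if (length(unlist(venn_sets, use.names = FALSE))) {
    as.list(venn_counts(venn_sets))
  } else list()
  writeLines(bona$targets,
             file.path(config$out_dir, "bona_fide_targets.txt"))

  status_counts <- table(factor(calls$status, levels = c(
    "up", "down", "not_significant", "filtered")))
  report <- list(
    tool = "peakforge", version = .PF_VERSION(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(confidence = config$confidence,
                      clusters = config$clusters,
                      annotation = config$annotation, deg = config$deg),
    input_checksums = as.list(tools::md5sum(unlist(Filter(Negate(is.null),
                                                          inputs)))),
    counts = list(
      tf_peaks_in = nrow(tf),
      k27_peaks_in = nrow(k27),
      high_confidence = nrow(conf$passing),
      stitched_regions = nrow(regions),
      clusters = sum(cl$regions$is_cluster),
      cluster_cutoff_score = cl$cutoff_score,
      category_distribution = dist,
      deg_status = as.list(status_counts),
      deg_up = length(up_genes), deg_down = length(down_genes),
      bound_genes = length(bound_genes),
      venn = venn,
      bona_fide_targets = length(bona$targets),
      bona_fide_fraction = bona$fraction_bound))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  .log("done: %d high-confidence peaks, %d clusters, %d bona fide targets",
       nrow(conf$passing), sum(cl$regions$is_cluster),
       length(bona$targets), verbose = verbose)
  invisible(report)
}
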