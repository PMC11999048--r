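# Enhancer-cluster (super-enhancer) identification by the rank-curve
# tangent method: stitch nearby peaks into regions, rank regions by
# aggregate score, map the rank-score curve onto the unit square, and call
# every region whose score exceeds the score at the first rank where the
# curve's slope exceeds the threshold (default 1, the unit-square diagonal).

#' Parameters of enhancer-cluster calling
#'
#' @param stitch_distance_bp Maximum edge-to-edge gap for merging adjacent
#'   peaks into one stitched region. Default 12500 bp, the conventional
#'   stitching distance for super-enhancer analysis.
#' @param slope_threshold Slope of the normalized rank-score curve above
#'   which the cutoff is placed. Default 1.
#' @param min_regions Below this many stitched regions no clusters are
#'   called. Default 3.
#' @return List of class \code{cluster_params}.
#' @export
cluster_params <- function(stitch_distance_bp = 12500, slope_threshold = 1,
                           min_regions = 3) {
  if (!is.numeric(stitch_distance_bp) || stitch_distance_bp < 0) {
    pf_config_error("stitch_distance_bp must be >= 0")
  }
  if (!is.numeric(slope_threshold) || slope_threshold <= 0) {
    pf_config_error("slope_threshold must be > 0")
  }
  structure(list(stitch_distance_bp = stitch_distance_bp,
                 slope_threshold = slope_threshold,
                 min_regions = min_regions),
            class = "cluster_params")
}

#' Stitch peaks into candidate regulatory regions
#'
#' Per chromosome, peaks sorted by position are merged while the
#' edge-to-edge gap to the growing region is <= \code{stitch_distance_bp}
#' (so overlapping or abutting peaks always merge). Each region spans the
#' hull of its members and carries the sum of member scores.
#'
#' @param peaks Peak data.frame (scores required).
#' @param stitch_distance_bp Maximum gap merged across, in bp.
#' @return data.frame of stitched regions sorted by (chrom, start):
#'   chrom, start, end, name, n_members, members (comma-separated peak
#'   names), score (aggregate).
#' @export
stitch_peaks <- function(peaks, stitch_distance_bp = 12500) {
  .check_peaks(peaks)
  if (!nrow(peaks)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      n_members = integer(), members = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  o <- order(peaks$chrom, peaks$start, peaks$end, method = "radix")
  p <- peaks[o, , drop = FALSE]
  new_region <- c(TRUE, p$chrom[-1L] != p$chrom[-nrow(p)] |
                    p$start[-1L] - cummax_by(p$end, p$chrom)[-nrow(p)] >
                    stitch_distance_bp)
  grp <- factor(cumsum(new_region), levels = unique(cumsum(new_region)))
  agg <- function(f, x) as.vector(tapply(x, grp, f))
  out <- data.frame(
    chrom = agg(function(x) x[1L], p$chrom),
    start = agg(min, p$start),
    end = agg(max, p$end),
    n_members = as.integer(agg(length, p$name)),
    members = as.vector(tapply(p$name, grp, paste, collapse = ",")),
    score = agg(sum, p$score),
    stringsAsFactors = FALSE)
  out$name <- sprintf("region_%d", seq_len(nrow(out)))
  out[, c("chrom", "start", "end", "name", "n_members", "members", "score")]
}

# running max of end coordinates, restarted at each chromosome change
cummax_by <- function(x, by) {
  out <- numeric(length(x))
  for (g in split(seq_along(x), by)) out[g] <- cummax(x[g])
  out
}

#' Build the normalized rank-score curve
#'
#' Regions are sorted ascending by aggregate score (ties broken by genomic
#' position) and placed on the unit square: \code{normalized_x = i/(N-1)}
#' for rank i in 0..N-1 (x = 0 when N = 1) and \code{normalized_y =
#' score / max(score)}.
#'
#' @param regions Stitched-region data.frame from \code{\link{stitch_peaks}}.
#' @return \code{regions} sorted by rank with columns rank, normalized_x,
#'   normalized_y added.
#' @export
build_rank_curve <- function(regions) {
  n <- nrow(regions)
  if (n < 1L) pf_domain_error("rank curve needs at least one region")
  if (max(regions$score) <= 0) {
    pf_domain_error("degenerate input: all aggregate scores are 0")
  }
  o <- order(regions$score, regions$chrom, regions$start, method = "radix")
  out <- regions[o, , drop = FALSE]
  out$rank <- seq_len(n) - 1L
  out$normalized_x <- if (n == 1L) 0 else out$rank / (n - 1L)
  out$normalized_y <- out$score / max(out$score)
  rownames(out) <- NULL
  out
}

# Central-difference slopes on the normalized curve; one-sided at the ends.
.curve_slopes <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  s <- numeric(n)
  s[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  s[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    s[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  }
  s
}

#' Call enhancer clusters on a rank curve
#'
#' The cutoff rank is the smallest rank whose curve slope (central
#' difference; one-sided at the ends) exceeds
#' \code{params$slope_threshold}; the cutoff score is the aggregate score
#' at that rank, and a region is a cluster iff its score strictly exceeds
#' the cutoff score (strictness keeps tied regions at the tangent point
#' out). With fewer than \code{min_regions} regions, or when no rank
#' qualifies, no clusters are called.
#'
#' @param regions Output of \code{\link{build_rank_curve}}.
#' @param params \code{\link{cluster_params}}.
#' @return List with \code{regions} (an added logical \code{is_cluster}
#'   column) and \code{cutoff_score} (number, or NA when no cutoff).
#' @export
call_clusters <- function(regions, params = cluster_params()) {
  if (is.null(regions$normalized_x)) {
    pf_domain_error("regions lack a rank curve; run build_rank_curve first")
  }
  n <- nrow(regions)
  regions$is_cluster <- FALSE
  if (n < params$min_regions) {
    return(list(regions = regions, cutoff_score = NA_real_))
  }
  s <- .curve_slopes(regions$normalized_x, regions$normalized_y)
  qual <- which(s > params$slope_threshold)
  if (!length(qual)) {
    return(list(regions = regions, cutoff_score = NA_real_))
  }
  cutoff_score <- regions$score[qual[1L]]
  regions$is_cluster <- regions$score > cutoff_score
  list(regions = regions, cutoff_score = cutoff_score)
}
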