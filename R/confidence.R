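# High-confidence TF peak filter: a peak passes iff (1) some H3K27ac peak
# lies within window_bp edge-to-edge (boundary inclusive, overlap = gap 0)
# and (2) the peak region fully contains at least one motif window. Both
# diagnostics are retained for every input peak so failing peaks remain
# auditable.

#' Parameters of the high-confidence peak filter
#'
#' @param window_bp Maximum edge-to-edge gap to the nearest H3K27ac peak,
#'   in bp; the comparison is inclusive (gap <= window passes). Default 500.
#' @param motif \code{motif_pattern} that must occur inside the peak
#'   region. Default: the GAS element TTCNNNGAA.
#' @param require_motif Set \code{FALSE} to filter on H3K27ac proximity
#'   alone.
#' @return List of class \code{confidence_params}.
#' @export
confidence_params <- function(window_bp = 500, motif = gas_motif(),
                              require_motif = TRUE) {
  if (!is.numeric(window_bp) || length(window_bp) != 1L ||
      is.na(window_bp) || window_bp < 0) {
    pf_config_error("window_bp must be a single number >= 0")
  }
  if (!inherits(motif, "motif_pattern")) {
    pf_config_error("motif must be a motif_pattern")
  }
  structure(list(window_bp = window_bp, motif = motif,
                 require_motif = isTRUE(require_motif)),
            class = "confidence_params")
}

#' Gap from a peak to its nearest feature
#'
#' Minimum edge-to-edge gap between \code{peak} and any same-chromosome
#' feature; \code{Inf} when no feature shares the chromosome.
#'
#' @param peak One-row peak data.frame (or list with chrom/start/end).
#' @param features Peak data.frame of features (may be empty).
#' @return Single non-negative number or \code{Inf}.
#' @export
nearest_feature_gap <- function(peak, features) {
  if (!nrow(features)) return(Inf)
  min(.gap_vec(peak$chrom, peak$start, peak$end,
               features$chrom, features$start, features$end))
}

# Vectorized nearest gaps for all peaks against one feature set. Features
# are pre-sorted per chromosome so each peak only inspects its flanking
# features rather than the whole set.
.nearest_gaps <- function(peaks, features) {
  gaps <- rep(Inf, nrow(peaks))
  if (!nrow(features)) return(gaps)
  by_chr <- split(seq_len(nrow(features)), features$chrom)
  for (chr in unique(peaks$chrom)) {
    fi <- by_chr[[chr]]
    if (is.null(fi)) next
    fs <- features$start[fi]; fe <- features$end[fi]
    o <- order(fs)
    fs <- fs[o]; fe <- fe[o]
    cummax_fe <- cummax(fe)
    pi <- which(peaks$chrom == chr)
    # left candidates have start <= peak end (any overlap nets gap 0);
    # right candidates start beyond the peak end
    k <- findInterval(peaks$end[pi], fs)
    left_gap <- ifelse(k >= 1L, peaks$start[pi] - cummax_fe[pmax(k, 1L)],
                       Inf)
    right_gap <- ifelse(k < length(fs),
                        fs[pmin(k + 1L, length(fs))] - peaks$end[pi], Inf)
    gaps[pi] <- pmax(0, pmin(left_gap, right_gap))
  }
  gaps
}

#' Identify high-confidence TF binding peaks
#'
#' A TF peak is high-confidence when it coincides with an H3K27ac mark
#' within \code{params$window_bp} (edge-to-edge, boundary inclusive) and
#' the peak region fully contains at least one motif window (unique
#' windows counted once even when both strands of a palindromic consensus
#' match).
#'
#' @param tf_peaks TF peak data.frame.
#' @param k27_peaks H3K27ac peak data.frame.
#' @param genome Named character vector of chromosome sequences; must cover
#'   every TF peak chromosome.
#' @param params \code{\link{confidence_params}}.
#' @return List with elements \code{audit} (one row per input TF peak:
#'   name, nearest_k27_gap, motif_hit_count, passed) and \code{passing}
#'   (the surviving peaks, input order preserved).
#' @export
filter_high_confidence <- function(tf_peaks, k27_peaks, genome,
                                   params = confidence_params()) {
  .check_peaks(tf_peaks, "TF peaks")
  .check_peaks(k27_peaks, "H3K27ac peaks")
  gaps <- .nearest_gaps(tf_peaks, k27_peaks)
  motif_n <- integer(nrow(tf_peaks))
  if (params$require_motif && nrow(tf_peaks)) {
    # one scan per chromosome, then count fully contained unique windows
    # per peak (equivalent to scan_intervals under the containment rule,
    # but without recompiling the pattern per region)
    L <- nchar(params$motif$symbols)
    for (chr in unique(tf_peaks$chrom)) {
      if (!chr %in% names(genome)) {
        pf_bounds_error(sprintf("peak chromosome '%s' not in genome", chr))
      }
      pi <- which(tf_peaks$chrom == chr)
      bad <- tf_peaks$end[pi] > nchar(genome[[chr]]) |
        tf_peaks$start[pi] < 0
      if (any(bad)) {
        i <- pi[bad][1L]
        pf_bounds_error(sprintf(
          "peak %s [%s, %s) outside chromosome '%s'", tf_peaks$name[i],
          tf_peaks$start[i], tf_peaks$end[i], chr))
      }
      hits <- scan_sequence(genome[[chr]], params$motif, "both")
      w <- sort(unique(hits$start))  # unique windows: presence semantics
      motif_n[pi] <- findInterval(tf_peaks$end[pi] - L, w) -
        findInterval(tf_peaks$start[pi] - 0.5, w)
    }
  }
  passed <- gaps <= params$window_bp &
    (!params$require_motif | motif_n >= 1L)
  audit <- data.frame(name = tf_peaks$name, nearest_k27_gap = gaps,
                      motif_hit_count = motif_n, passed = passed,
                      stringsAsFactors = FALSE)
  list(audit = audit,
       passing = tf_peaks[passed, , drop = FALSE])
}
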