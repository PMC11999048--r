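# Genomic intervals are 0-based half-open [start, end), the BED convention,
# everywhere in this package. 1-based inputs are never auto-detected.

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open \code{[start, end)} (BED convention).
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start (>= 0).
#' @param end 0-based exclusive end (> start).
#' @return A list of class \code{genomic_interval} with fields
#'   \code{chrom}, \code{start}, \code{end}.
#' @examples
#' genomic_interval("chr1", 100, 200)
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
      !nzchar(chrom)) {
    pf_domain_error("chrom must be a non-empty string")
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start) {
    pf_domain_error(sprintf(
      "invalid interval [%s, %s): need 0 <= start < end", start, end))
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' Edge-to-edge gap between two genomic intervals
#'
#' Returns 0 when the intervals overlap or abut, the number of intervening
#' bases otherwise, and \code{Inf} (the different-chromosome sentinel) when
#' the intervals lie on different chromosomes. Symmetric in its arguments.
#'
#' @param a,b \code{genomic_interval} objects, or lists/one-row data frames
#'   with \code{chrom}, \code{start}, \code{end} fields.
#' @return Non-negative number of intervening bp, or \code{Inf}.
#' @examples
#' interval_gap(genomic_interval("chr1", 100, 200),
#'              genomic_interval("chr1", 700, 800))  # 500
#' @export
interval_gap <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(Inf)
  max(0, max(a$start, b$start) - min(a$end, b$end))
}

# Vectorized gap between one interval and many (same-length vectors).
# Different chromosome -> Inf.
.gap_vec <- function(chrom, start, end, chroms, starts, ends) {
  g <- pmax(0, pmax(start, starts) - pmin(end, ends))
  g[chroms != chrom] <- Inf
  g
}

# Validate a peak data.frame (chrom, start, end, name, score, strand).
.check_peaks <- function(peaks, what = "peaks") {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    pf_domain_error(sprintf("%s missing columns: %s", what,
                            paste(miss, collapse = ", ")))
  }
  if (nrow(peaks)) {
    if (any(peaks$start < 0) || any(peaks$end <= peaks$start)) {
      pf_domain_error(sprintf("%s contain invalid intervals", what))
    }
    if (any(peaks$score < 0)) {
      pf_domain_error(sprintf("%s contain negative scores", what))
    }
  }
  invisible(peaks)
}

# Empty peak set with the canonical columns.
.empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}
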