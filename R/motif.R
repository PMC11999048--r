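# IUPAC degenerate consensus matching. The workhorse use case is the GAS
# element 5'-TTCNNNGAA-3', the palindromic site bound by STAT dimers, but
# arbitrary IUPAC patterns are supported. Matching is exact-symbol: no
# mismatches, no position weights. A genome N matches no pattern symbol
# (pattern N means "any real base"), so masked regions never produce hits.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N")

#' Construct an IUPAC motif pattern
#'
#' @param symbols Consensus string over the IUPAC alphabet
#'   (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N), length >= 1.
#' @param label Optional human-readable label.
#' @return Object of class \code{motif_pattern}.
#' @examples
#' motif_pattern("TTCNNNGAA", "GAS")
#' @export
motif_pattern <- function(symbols, label = symbols) {
  symbols <- toupper(symbols)
  if (!is.character(symbols) || length(symbols) != 1L || !nzchar(symbols)) {
    pf_domain_error("motif pattern must be a non-empty string")
  }
  sym <- strsplit(symbols, "")[[1L]]
  bad <- !sym %in% names(.IUPAC)
  if (any(bad)) {
    pf_domain_error(sprintf("invalid IUPAC symbol '%s' in pattern '%s'",
                            sym[bad][1L], symbols))
  }
  structure(list(symbols = symbols, label = label), class = "motif_pattern")
}

#' The GAS element consensus, TTCNNNGAA
#' @return \code{motif_pattern} for the GAS element.
#' @export
gas_motif <- function() motif_pattern("TTCNNNGAA", "GAS")

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern %s: 5'-%s-3'>\n", x$label, x$symbols))
  invisible(x)
}

#' Reverse complement of an IUPAC pattern
#'
#' Symbols are reversed and complemented under the IUPAC complement rules
#' (R<->Y, K<->M, B<->V, D<->H; A<->T, C<->G; N, S, W self-complementary).
#' The GAS consensus TTCNNNGAA is its own reverse complement.
#'
#' @param pattern A \code{motif_pattern}.
#' @return A \code{motif_pattern}.
#' @export
reverse_complement <- function(pattern) {
  sym <- rev(strsplit(pattern$symbols, "")[[1L]])
  motif_pattern(paste(.IUPAC_COMPLEMENT[sym], collapse = ""),
                label = paste0(pattern$label, "_rc"))
}

# PCRE character-class regex for one pattern; overlapping matches are found
# with a capturing lookahead.
.motif_regex <- function(pattern) {
  sym <- strsplit(pattern$symbols, "")[[1L]]
  paste0("(?=(", paste(vapply(sym, function(s) {
    b <- .IUPAC[[s]]
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, ""), collapse = ""), "))")
}

.empty_hits <- function() {
  data.frame(start = numeric(), end = numeric(), strand = character(),
             matched = character(), stringsAsFactors = FALSE)
}

# forward-strand window starts (0-based) of pattern in sequence
.scan_starts <- function(sequence, pattern) {
  m <- gregexpr(.motif_regex(pattern), sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for an IUPAC motif
#'
#' A window matches on the + strand iff every base satisfies the
#' corresponding pattern symbol; it matches on the - strand iff the forward
#' strand matches \code{reverse_complement(pattern)} there. Overlapping
#' matches are all reported. Hits are sorted by start, then strand
#' (+ before -). \code{matched} is always the forward-strand sequence of
#' the window. Offsets are 0-based relative to the sequence start.
#'
#' @param sequence String over \{A,C,G,T,N\} (lowercase accepted).
#' @param pattern A \code{motif_pattern}.
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @return data.frame with columns start, end, strand, matched. A pattern
#'   longer than the sequence yields zero hits, not an error.
#' @examples
#' scan_sequence("GTTTCTTCTGAGAAGTACC", gas_motif(), "forward")
#' @export
scan_sequence <- function(sequence, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  sequence <- toupper(sequence)
  L <- nchar(pattern$symbols)
  if (nchar(sequence) < L) return(.empty_hits())
  fwd <- .scan_starts(sequence, pattern)
  hits <- data.frame(start = as.numeric(fwd),
                     strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
  if (strands == "both") {
    rev_ <- .scan_starts(sequence, reverse_complement(pattern))
    hits <- rbind(hits, data.frame(start = as.numeric(rev_),
                                   strand = rep("-", length(rev_)),
                                   stringsAsFactors = FALSE))
  }
  if (!nrow(hits)) return(.empty_hits())
  hits <- hits[order(hits$start, hits$strand, method = "radix"), ,
               drop = FALSE]
  data.frame(start = hits$start, end = hits$start + L, strand = hits$strand,
             matched = substring(sequence, hits$start + 1, hits$start + L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan genomic regions for an IUPAC motif
#'
#' Only windows fully contained in a region are reported; a window split by
#' the region boundary does not count. Coordinates in the result are
#' genomic (region start + in-region offset).
#'
#' @param genome Named character vector, chromosome -> sequence.
#' @param regions data.frame with chrom, start, end (and optionally name).
#' @param pattern A \code{motif_pattern}.
#' @param strands \code{"both"} or \code{"forward"}.
#' @return data.frame with columns region (name, or \code{region_<i>}),
#'   chrom, start, end, strand, matched.
#' @export
scan_intervals <- function(genome, regions, pattern,
                           strands = c("both", "forward")) {
  strands <- match.arg(strands)
  rname <- if (!is.null(regions$name)) regions$name else
    paste0("region_", seq_len(nrow(regions)))
  L <- nchar(pattern$symbols)
  rc <- reverse_complement(pattern)
  acc_region <- acc_chrom <- acc_strand <- vector("list", nrow(regions))
  acc_start <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chr <- regions$chrom[i]
    if (!chr %in% names(genome)) {
      pf_bounds_error(sprintf("region %s: chromosome '%s' not in genome",
                              rname[i], chr))
    }
    if (regions$end[i] > nchar(genome[[chr]]) || regions$start[i] < 0) {
      pf_bounds_error(sprintf(
        "region %s [%s, %s) outside chromosome '%s' (length %d)",
        rname[i], regions$start[i], regions$end[i], chr,
        nchar(genome[[chr]])))
    }
    if (regions$end[i] - regions$start[i] < L) next
    sub <- substr(genome[[chr]], regions$start[i] + 1, regions$end[i])
    fwd <- .scan_starts(sub, pattern)
    starts <- as.numeric(fwd)
    strand <- rep("+", length(fwd))
    if (strands == "both") {
      rev_ <- as.numeric(.scan_starts(sub, rc))
      starts <- c(starts, rev_)
      strand <- c(strand, rep("-", length(rev_)))
    }
    if (!length(starts)) next
    o <- order(starts, strand, method = "radix")
    acc_region[[i]] <- rep(rname[i], length(starts))
    acc_chrom[[i]] <- rep(chr, length(starts))
    acc_start[[i]] <- starts[o] + regions$start[i]
    acc_strand[[i]] <- strand[o]
  }
  start <- unlist(acc_start) %||% numeric(0)
  chrom <- unlist(acc_chrom) %||% character(0)
  out <- data.frame(region = unlist(acc_region) %||% character(0),
                    chrom = chrom, start = start, end = start + L,
                    strand = unlist(acc_strand) %||% character(0),
                    stringsAsFactors = FALSE)
  out$matched <- if (nrow(out)) {
    substring(genome[out$chrom], out$start + 1, out$start + L)
  } else character(0)
  rownames(out) <- NULL
  out
}
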