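# Readers/writers for the plain-text formats the pipeline consumes: FASTA,
# BED3/5/6 (+extra columns), 4-column bedGraph, and the tab-delimited
# gene-model table. Parsing is deliberately strict: malformed lines raise
# pf_format_error with enough context to locate the offender.

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and restricted to the \{A,C,G,T,N\} alphabet.
#' Headers are parsed up to the first whitespace; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) pf_io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- startsWith(lines, ">")
  if (!any(hdr) || !hdr[1L]) {
    pf_format_error(sprintf("%s: not FASTA (no leading '>')", path))
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids)) {
    pf_format_error(sprintf("%s: duplicate FASTA header '%s'",
                            path, ids[duplicated(ids)][1L]))
  }
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  # records with no body lines (trailing empty record) become ""
  out <- setNames(character(length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  bad <- regexpr("[^ACGTN]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    pf_format_error(sprintf(
      "%s: record '%s' has non-IUPAC character '%s' at offset %d",
      path, ids[i], substr(out[i], bad[i], bad[i]), bad[i] - 1L))
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "wb")  # "wb": byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 if (n) substring(s, starts, pmin(starts + width - 1L, n))),
               con)
  }
  invisible(path)
}

.split_tsv <- function(path) {
  if (!file.exists(path)) pf_io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

.as_coord <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)) || any(v != floor(v))) {
    pf_format_error(sprintf("%s line %d: non-integer %s '%s'",
                            path, lineno[which(is.na(v) | v != floor(v))][1L],
                            what, x[which(is.na(v) | v != floor(v))][1L]))
  }
  v
}

#' Read a BED file of peaks
#'
#' Columns are mapped BED-style (chrom, start, end, name, score, strand);
#' coordinates are kept 0-based half-open verbatim. Missing names are
#' auto-generated as \code{peak_<index>} (1-based); missing scores default
#' to 0; missing strands to ".". Duplicate names are made unique by
#' suffixing, since downstream joins are keyed by name.
#'
#' @param path Path to a tab-delimited BED file.
#' @param min_cols Minimum required column count: 3, 5 or 6.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path, min_cols = 3L) {
  if (!min_cols %in% c(3L, 5L, 6L)) {
    pf_domain_error("min_cols must be one of 3, 5, 6")
  }
  fields <- .split_tsv(path)
  if (!length(fields)) return(.empty_peaks())
  ncols <- lengths(fields)
  if (any(ncols < min_cols)) {
    pf_format_error(sprintf("%s line %d: expected >= %d columns, found %d",
                            path, which(ncols < min_cols)[1L], min_cols,
                            min(ncols)))
  }
  lineno <- seq_along(fields)
  col <- function(k, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= k) f[[k]] else default, "")
  }
  chrom <- col(1L)
  start <- .as_coord(col(2L), path, lineno, "start coordinate")
  end <- .as_coord(col(3L), path, lineno, "end coordinate")
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    pf_format_error(sprintf("%s line %d: invalid interval [%s, %s)",
                            path, bad[1L], start[bad[1L]], end[bad[1L]]))
  }
  name <- col(4L)
  name[is.na(name) | !nzchar(name)] <-
    paste0("peak_", lineno[is.na(name) | !nzchar(name)])
  if (anyDuplicated(name)) name <- make.unique(name, sep = "_dup")
  score <- suppressWarnings(as.numeric(col(5L, "0")))
  if (any(is.na(score))) {
    pf_format_error(sprintf("%s line %d: non-numeric score",
                            path, which(is.na(score))[1L]))
  }
  strand <- col(6L, ".")
  strand[is.na(strand)] <- "."
  if (!all(strand %in% c("+", "-", "."))) {
    pf_format_error(sprintf("%s line %d: invalid strand", path,
                            which(!strand %in% c("+", "-", "."))[1L]))
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, strand = strand, stringsAsFactors = FALSE)
}

# Deterministic numeric formatting for text output (no scientific notation,
# trailing zeros trimmed). Integral values print without a decimal point.
.fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         sprintf("%.0f", x),
         sprintf("%.10g", x))
}

#' Write peaks as BED
#'
#' Emits 6 columns (chrom, start, end, name, score, strand) plus any
#' \code{extra_columns} appended after column 6. Round-trips through
#' \code{\link{read_bed}} field-for-field.
#'
#' @param peaks Peak data.frame.
#' @param path Output path.
#' @param extra_columns Optional named list/data.frame of extra columns,
#'   each of length \code{nrow(peaks)}.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(peaks, path, extra_columns = NULL) {
  .check_peaks(peaks)
  cols <- list(peaks$chrom, .fmt_num(peaks$start), .fmt_num(peaks$end),
               peaks$name, .fmt_num(peaks$score), peaks$strand)
  if (!is.null(extra_columns)) {
    for (nm in names(extra_columns)) {
      v <- extra_columns[[nm]]
      if (length(v) != nrow(peaks)) {
        pf_domain_error(sprintf("extra column '%s' has length %d, need %d",
                                nm, length(v), nrow(peaks)))
      }
      cols <- c(cols, list(if (is.numeric(v)) .fmt_num(v) else as.character(v)))
    }
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) pf_io_error(conditionMessage(e)))
  on.exit(close(con))
  if (nrow(peaks)) writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a 4-column bedGraph coverage file
#'
#' Steps must be sorted and non-overlapping within each chromosome.
#'
#' @param path Path to a bedGraph file.
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  fields <- .split_tsv(path)
  if (!length(fields)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (any(lengths(fields) < 4L)) {
    pf_format_error(sprintf("%s line %d: expected 4 columns", path,
                            which(lengths(fields) < 4L)[1L]))
  }
  lineno <- seq_along(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .as_coord(vapply(fields, `[[`, "", 2L), path, lineno, "start")
  end <- .as_coord(vapply(fields, `[[`, "", 3L), path, lineno, "end")
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  if (any(is.na(value))) {
    pf_format_error(sprintf("%s line %d: non-numeric value", path,
                            which(is.na(value))[1L]))
  }
  if (any(start >= end)) {
    pf_format_error(sprintf("%s line %d: invalid step interval", path,
                            which(start >= end)[1L]))
  }
  cov <- data.frame(chrom = chrom, start = start, end = end, value = value,
                    stringsAsFactors = FALSE)
  .check_coverage(cov, path)
  cov
}

.check_coverage <- function(cov, what = "coverage") {
  for (chr in unique(cov$chrom)) {
    sub <- cov[cov$chrom == chr, , drop = FALSE]
    o <- order(sub$start)
    sub <- sub[o, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      pf_format_error(sprintf("%s: overlapping coverage steps on %s",
                              what, chr))
    }
  }
  invisible(cov)
}

#' Write coverage steps as bedGraph
#' @param coverage data.frame with chrom, start, end, value.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bedgraph <- function(coverage, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(coverage)) {
    writeLines(paste(coverage$chrom, .fmt_num(coverage$start),
                     .fmt_num(coverage$end), .fmt_num(coverage$value),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Score peaks from bedGraph coverage
#'
#' Replaces each peak score by the coverage integral over the peak:
#' \eqn{\sum_{steps} value \times overlap\_width}. Peaks with no overlapping
#' steps score 0. The score is additive over disjoint sub-intervals.
#'
#' @param peaks Peak data.frame.
#' @param coverage Coverage data.frame (chrom, start, end, value), sorted
#'   and non-overlapping per chromosome.
#' @return \code{peaks} with the \code{score} column replaced.
#' @export
score_peaks_from_coverage <- function(peaks, coverage) {
  .check_peaks(peaks)
  .check_coverage(coverage)
  score <- numeric(nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chr)
    sub <- coverage[coverage$chrom == chr, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$start), , drop = FALSE]
    for (i in pi) {
      ov <- pmin(peaks$end[i], sub$end) - pmax(peaks$start[i], sub$start)
      ov[ov < 0] <- 0
      score[i] <- sum(ov * sub$value)
    }
  }
  peaks$score <- score
  peaks
}

#' Read the tab-delimited gene-model table
#'
#' Expected header: gene_id, chrom, strand, tx_start, tx_end, cds_start,
#' cds_end, exon_sizes, exon_starts. Exon blocks are BED12-like
#' comma-separated sizes and starts (starts relative to tx_start). Empty
#' cds fields denote a non-coding gene. Gene invariants (sorted,
#' non-overlapping exons inside the transcript span; cds endpoints inside
#' the exon union) are enforced.
#'
#' @param path Path to the gene table.
#' @return data.frame of gene models, one row per gene.
#' @export
read_gene_table <- function(path) {
  fields <- .split_tsv(path)
  if (!length(fields)) pf_format_error(sprintf("%s: empty gene table", path))
  header <- fields[[1L]]
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_sizes", "exon_starts")
  if (!all(need %in% header)) {
    pf_format_error(sprintf("%s: gene table header missing: %s", path,
                            paste(setdiff(need, header), collapse = ", ")))
  }
  body <- fields[-1L]
  if (!length(body)) {
    return(.empty_genes())
  }
  idx <- match(need, header)
  get <- function(k) vapply(body, function(f) {
    if (length(f) >= k) f[[k]] else ""
  }, "")
  g <- data.frame(
    gene_id = get(idx[1L]), chrom = get(idx[2L]), strand = get(idx[3L]),
    tx_start = suppressWarnings(as.numeric(get(idx[4L]))),
    tx_end = suppressWarnings(as.numeric(get(idx[5L]))),
    cds_start = suppressWarnings(as.numeric(get(idx[6L]))),
    cds_end = suppressWarnings(as.numeric(get(idx[7L]))),
    exon_sizes = get(idx[8L]), exon_starts = get(idx[9L]),
    stringsAsFactors = FALSE)
  validate_genes(g, path)
  g
}

.empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
             tx_start = numeric(), tx_end = numeric(), cds_start = numeric(),
             cds_end = numeric(), exon_sizes = character(),
             exon_starts = character(), stringsAsFactors = FALSE)
}

#' Validate a gene-model table
#' @param genes Gene data.frame as produced by \code{\link{read_gene_table}}.
#' @param context Label used in error messages.
#' @return Invisibly, \code{genes}.
#' @export
validate_genes <- function(genes, context = "gene table") {
  for (i in seq_len(nrow(genes))) {
    id <- genes$gene_id[i]
    if (!genes$strand[i] %in% c("+", "-")) {
      pf_format_error(sprintf("%s: gene %s has invalid strand", context, id))
    }
    if (is.na(genes$tx_start[i]) || is.na(genes$tx_end[i]) ||
        genes$tx_start[i] < 0 || genes$tx_end[i] <= genes$tx_start[i]) {
      pf_format_error(sprintf("%s: gene %s has invalid transcript span",
                              context, id))
    }
    ex <- gene_exons(genes[i, ])
    if (!nrow(ex)) {
      pf_format_error(sprintf("%s: gene %s has no exons", context, id))
    }
    if (any(diff(ex$start) <= 0) && nrow(ex) > 1L) {
      pf_format_error(sprintf("%s: gene %s exons not sorted", context, id))
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      pf_format_error(sprintf("%s: gene %s exons overlap", context, id))
    }
    if (ex$start[1L] < genes$tx_start[i] ||
        ex$end[nrow(ex)] > genes$tx_end[i]) {
      pf_format_error(sprintf("%s: gene %s exon outside transcript span",
                              context, id))
    }
    cs <- genes$cds_start[i]; ce <- genes$cds_end[i]
    if (xor(is.na(cs), is.na(ce))) {
      pf_format_error(sprintf("%s: gene %s has half-specified cds",
                              context, id))
    }
    if (!is.na(cs)) {
      if (cs >= ce || cs < genes$tx_start[i] || ce > genes$tx_end[i]) {
        pf_format_error(sprintf("%s: gene %s cds outside transcript",
                                context, id))
      }
      in_exon <- function(p) any(ex$start <= p & p < ex$end)
      if (!in_exon(cs) || !in_exon(ce - 1)) {
        pf_format_error(sprintf(
          "%s: gene %s cds endpoints not inside exons", context, id))
      }
    }
  }
  invisible(genes)
}

#' Exon intervals of one gene (genomic coordinates)
#' @param gene One-row gene data.frame.
#' @return data.frame with columns start, end (0-based half-open).
#' @export
gene_exons <- function(gene) {
  sizes <- as.numeric(strsplit(gene$exon_sizes, ",", fixed = TRUE)[[1L]])
  starts <- as.numeric(strsplit(gene$exon_starts, ",", fixed = TRUE)[[1L]])
  if (length(sizes) != length(starts) || any(is.na(sizes)) ||
      any(is.na(starts)) || any(sizes <= 0)) {
    pf_format_error(sprintf("gene %s: malformed exon blocks", gene$gene_id))
  }
  data.frame(start = gene$tx_start + starts,
             end = gene$tx_start + starts + sizes)
}

#' Strand-aware transcription start site of each gene
#' @param genes Gene data.frame.
#' @return Numeric vector of TSS positions (0-based): \code{tx_start} on +
#'   and \code{tx_end - 1} on -.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
}

#' Write a gene-model table
#' @param genes Gene data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_table <- function(genes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  fmt_cds <- function(x) ifelse(is.na(x), "", .fmt_num(x))
  writeLines(c(paste(c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                       "cds_start", "cds_end", "exon_sizes", "exon_starts"),
                     collapse = "\t"),
               if (nrow(genes)) {
                 paste(genes$gene_id, genes$chrom, genes$strand,
                       .fmt_num(genes$tx_start), .fmt_num(genes$tx_end),
                       fmt_cds(genes$cds_start), fmt_cds(genes$cds_end),
                       genes$exon_sizes, genes$exon_starts, sep = "\t")
               }), con)
  invisible(path)
}
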