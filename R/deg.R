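# Expression-side computation: a low-count prefilter, Benjamini-Hochberg
# step-up adjustment applied to the genes that survive the prefilter
# (independent-filtering order), strict fold-change / adjusted-p
# thresholds, Venn decomposition of gene lists, and intersection with
# ChIP-bound genes to nominate bona fide targets.

#' Parameters of DEG calling
#'
#' @param min_total_count Genes with fewer total raw reads are removed
#'   before testing (inclusive threshold: \code{total >= min} is kept).
#'   Default 10.
#' @param lfc_threshold Absolute log2 fold-change bound; the comparison is
#'   strict (\code{log2fc > t} or \code{< -t}). Default 1.
#' @param padj_threshold Adjusted-p bound; strict (\code{padj < alpha}).
#'   Default 0.05.
#' @return List of class \code{deg_params}.
#' @export
deg_params <- function(min_total_count = 10, lfc_threshold = 1,
                       padj_threshold = 0.05) {
  if (min_total_count < 0) pf_config_error("min_total_count must be >= 0")
  if (lfc_threshold <= 0) pf_config_error("lfc_threshold must be > 0")
  if (padj_threshold <= 0) pf_config_error("padj_threshold must be > 0")
  structure(list(min_total_count = min_total_count,
                 lfc_threshold = lfc_threshold,
                 padj_threshold = padj_threshold),
            class = "deg_params")
}

.check_deg_stats <- function(stats) {
  need <- c("gene_id", "total_count", "log2fc", "pvalue")
  miss <- setdiff(need, names(stats))
  if (length(miss)) {
    pf_domain_error(sprintf("DEG stats missing columns: %s",
                            paste(miss, collapse = ", ")))
  }
  if (nrow(stats) &&
      (any(stats$pvalue < 0, na.rm = TRUE) ||
       any(stats$pvalue > 1, na.rm = TRUE))) {
    pf_domain_error("p-values must lie in [0, 1]")
  }
  invisible(stats)
}

#' Low-count prefilter
#'
#' @param stats data.frame with gene_id, total_count, log2fc, pvalue.
#' @param params \code{\link{deg_params}}.
#' @return List with \code{kept} and \code{filtered} data.frames, input
#'   order preserved in each.
#' @export
filter_low_counts <- function(stats, params = deg_params()) {
  .check_deg_stats(stats)
  keep <- stats$total_count >= params$min_total_count
  list(kept = stats[keep, , drop = FALSE],
       filtered = stats[!keep, , drop = FALSE])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{q_(i) = min_(j >= i) p_(j) * n / j}, capped at 1, computed on the
#' ascending order statistics and mapped back to the input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    pf_domain_error("p-values must lie in [0, 1]")
  }
  n <- length(pvalues)
  o <- order(pvalues)
  q <- pmin(1, rev(cummin(rev(pvalues[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- q
  out
}

#' Call differentially expressed genes
#'
#' Pipeline: prefilter on total counts, BH adjustment over the kept genes
#' only, then strict thresholds: status \code{up} iff \code{log2fc >
#' lfc_threshold} and \code{padj < padj_threshold}; \code{down} iff
#' \code{log2fc < -lfc_threshold} and \code{padj < padj_threshold};
#' prefiltered genes carry status \code{filtered} and no padj.
#'
#' @param stats data.frame with gene_id, total_count, log2fc, pvalue.
#' @param params \code{\link{deg_params}}.
#' @return \code{stats} with columns padj and status added, input order
#'   preserved.
#' @export
call_degs <- function(stats, params = deg_params()) {
  .check_deg_stats(stats)
  out <- stats
  out$padj <- NA_real_
  out$status <- rep("filtered", nrow(stats))
  keep <- stats$total_count >= params$min_total_count
  if (any(keep)) {
    padj <- bh_adjust(stats$pvalue[keep])
    out$padj[keep] <- padj
    sig <- padj < params$padj_threshold
    lfc <- stats$log2fc[keep]
    st <- rep("not_significant", sum(keep))
    st[sig & lfc > params$lfc_threshold] <- "up"
    st[sig & lfc < -params$lfc_threshold] <- "down"
    out$status[keep] <- st
  }
  out
}

#' Exclusive Venn region counts for 2-5 gene sets
#'
#' @param named_sets Named list of 2-5 character vectors.
#' @return Named integer vector over all \code{2^k - 1} exclusive
#'   membership signatures; signature names join the member set names with
#'   \code{"&"} in input order. Region counts sum to the union size.
#' @export
venn_counts <- function(named_sets) {
  k <- length(named_sets)
  if (k < 2L || k > 5L) {
    pf_domain_error("venn_counts supports 2 to 5 sets")
  }
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets)))) {
    pf_domain_error("sets must be named")
  }
  named_sets <- lapply(named_sets, unique)
  universe <- unique(unlist(named_sets, use.names = FALSE))
  member <- vapply(named_sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  sigs <- unlist(lapply(seq_len(k), function(m) {
    combn(names(named_sets), m, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- setNames(integer(length(sigs)), sigs)
  if (length(universe)) {
    got <- apply(member, 1L, function(row) {
      paste(names(named_sets)[row], collapse = "&")
    })
    tab <- table(got)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Intersect DEGs with ChIP-bound genes
#'
#' @param deg_genes Character vector of DEG gene ids.
#' @param bound_genes Character vector of bound gene ids.
#' @return List with \code{targets} (sorted intersection) and
#'   \code{fraction_bound} (\code{|intersection| / |deg_genes|}; 0 when
#'   the DEG set is empty).
#' @export
bona_fide_targets <- function(deg_genes, bound_genes) {
  deg_genes <- unique(deg_genes)
  inter <- sort(intersect(deg_genes, unique(bound_genes)))
  frac <- if (length(deg_genes)) length(inter) / length(deg_genes) else 0
  list(targets = inter, fraction_bound = frac)
}

#' Read a per-gene DEG statistics table
#'
#' Tab-delimited with header gene_id, total_count, log2fc, pvalue.
#'
#' @param path Path to the TSV.
#' @return data.frame of DEG statistics.
#' @export
read_deg_stats <- function(path) {
  fields <- .split_tsv(path)
  if (!length(fields)) pf_format_error(sprintf("%s: empty DEG table", path))
  header <- fields[[1L]]
  need <- c("gene_id", "total_count", "log2fc", "pvalue")
  if (!all(need %in% header)) {
    pf_format_error(sprintf("%s: DEG table header missing: %s", path,
                            paste(setdiff(need, header), collapse = ", ")))
  }
  body <- fields[-1L]
  idx <- match(need, header)
  get <- function(k) vapply(body, `[[`, "", k)
  stats <- data.frame(
    gene_id = get(idx[1L]),
    total_count = suppressWarnings(as.numeric(get(idx[2L]))),
    log2fc = suppressWarnings(as.numeric(get(idx[3L]))),
    pvalue = suppressWarnings(as.numeric(get(idx[4L]))),
    stringsAsFactors = FALSE)
  if (any(is.na(stats$total_count)) || any(is.na(stats$log2fc)) ||
      any(is.na(stats$pvalue))) {
    pf_format_error(sprintf("%s: non-numeric DEG statistics", path))
  }
  .check_deg_stats(stats)
  stats
}

#' Write a per-gene DEG statistics or calls table
#' @param stats data.frame to write (all columns emitted).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_deg_table <- function(stats, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  cols <- lapply(stats, function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "NA", .fmt_num(v)) else as.character(v)
  })
  writeLines(c(paste(names(stats), collapse = "\t"),
               if (nrow(stats)) do.call(paste, c(cols, sep = "\t"))), con)
  invisible(path)
}
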