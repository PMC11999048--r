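# Peak-to-gene annotation. Each peak is assigned exactly one category from
# its midpoint so category counts partition the peak set (a pie chart sums
# to 100%): promoter > 3'UTR > exon > intron > distal > intergenic.
# 5'UTR territory is exonic and therefore reported as exon; the 3'UTR is
# the strand-aware exon portion between the CDS end and the transcript end,
# so non-coding genes contribute no 3'UTR territory.

#' Parameters of peak annotation
#'
#' @param promoter_upstream_bp Promoter window extent upstream of the TSS
#'   (strand-aware). Default 1000.
#' @param promoter_downstream_bp Promoter window extent downstream of the
#'   TSS. Default 100.
#' @param distal_max_bp A midpoint within this many bp upstream of a TSS
#'   (and in no higher category) is a distal/putative-enhancer peak.
#'   Default 50000.
#' @param link_max_bp Upper bound on the |TSS distance| of any peak-gene
#'   link. Default 100000. Must be >= \code{distal_max_bp}.
#' @return List of class \code{annotation_params}.
#' @export
annotation_params <- function(promoter_upstream_bp = 1000,
                              promoter_downstream_bp = 100,
                              distal_max_bp = 50000,
                              link_max_bp = 100000) {
  vals <- c(promoter_upstream_bp, promoter_downstream_bp,
            distal_max_bp, link_max_bp)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    pf_config_error("annotation windows must be finite and >= 0")
  }
  if (distal_max_bp > link_max_bp) {
    pf_config_error("distal_max_bp must be <= link_max_bp")
  }
  structure(list(promoter_upstream_bp = promoter_upstream_bp,
                 promoter_downstream_bp = promoter_downstream_bp,
                 distal_max_bp = distal_max_bp,
                 link_max_bp = link_max_bp),
            class = "annotation_params")
}

.CATEGORIES <- c("promoter", "three_prime_utr", "exon", "intron",
                 "distal", "intergenic")

#' Strand-aware promoter window of a gene
#'
#' On + : \code{[TSS - upstream, TSS + downstream)}; on - the mirror image
#' \code{[TSS - downstream + 1, TSS + upstream + 1)}. Clipped at 0.
#'
#' @param gene One-row gene data.frame.
#' @param params \code{\link{annotation_params}}.
#' @return \code{genomic_interval} of the promoter window.
#' @export
promoter_window <- function(gene, params = annotation_params()) {
  tss <- gene_tss(gene)
  up <- params$promoter_upstream_bp
  down <- params$promoter_downstream_bp
  if (gene$strand == "+") {
    s <- tss - up; e <- tss + down
  } else {
    s <- tss - down + 1; e <- tss + up + 1
  }
  genomic_interval(gene$chrom, max(0, s), e)
}

# Feature table: one row per (gene, feature interval) with the category
# priority rank. Built once per gene set, then queried per midpoint.
.feature_table <- function(genes, params) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- gene_exons(g)
    tss <- gene_tss(g)
    pw <- promoter_window(g, params)
    feats <- data.frame(start = pw$start, end = pw$end, rank = 1L)
    if (!is.na(g$cds_start)) {
      if (g$strand == "+") {
        u3s <- g$cds_end; u3e <- g$tx_end
      } else {
        u3s <- g$tx_start; u3e <- g$cds_start
      }
      s <- pmax(ex$start, u3s); e <- pmin(ex$end, u3e)
      keep <- s < e
      if (any(keep)) {
        feats <- rbind(feats, data.frame(start = s[keep], end = e[keep],
                                         rank = 2L))
      }
    }
    feats <- rbind(feats,
                   data.frame(start = ex$start, end = ex$end, rank = 3L),
                   data.frame(start = g$tx_start, end = g$tx_end, rank = 4L))
    # distal territory: strand-aware upstream of the TSS
    if (params$distal_max_bp > 0) {
      ds <- if (g$strand == "+") {
        c(max(0, tss - params$distal_max_bp), tss)
      } else {
        c(tss + 1, tss + 1 + params$distal_max_bp)
      }
      if (ds[2L] > ds[1L]) {
        feats <- rbind(feats, data.frame(start = ds[1L], end = ds[2L],
                                         rank = 5L))
      }
    }
    feats$gene <- g$gene_id
    feats$chrom <- g$chrom
    feats$tss <- tss
    feats$strand <- g$strand
    rows[[i]] <- feats
  }
  do.call(rbind, rows)
}

#' Classify peaks into genomic categories and link target genes
#'
#' Classification uses the peak midpoint, \code{floor((start + end) / 2)}.
#' Category priority is promoter > three_prime_utr > exon > intron >
#' distal > intergenic; among genes offering the winning category, ties
#' break by smaller |TSS distance|, then lexicographic gene id. TSS
#' distance is strand-aware and signed, negative upstream of the TSS.
#' Peaks matching no gene feature are intergenic with no target gene.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene data.frame (see \code{\link{read_gene_table}}).
#' @param params \code{\link{annotation_params}}.
#' @return data.frame with one row per peak: name, chrom, midpoint,
#'   category, target_gene (NA for intergenic), tss_distance (NA for
#'   intergenic).
#' @export
classify_peaks <- function(peaks, genes, params = annotation_params()) {
  .check_peaks(peaks)
  out <- data.frame(name = peaks$name, chrom = peaks$chrom,
                    midpoint = floor((peaks$start + peaks$end) / 2),
                    category = rep("intergenic", nrow(peaks)),
                    target_gene = rep(NA_character_, nrow(peaks)),
                    tss_distance = rep(NA_real_, nrow(peaks)),
                    stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(genes)) return(out)
  feats <- .feature_table(genes, params)
  for (chr in unique(out$chrom)) {
    fi <- feats[feats$chrom == chr, , drop = FALSE]
    if (!nrow(fi)) next
    pi <- which(out$chrom == chr)
    mids <- out$midpoint[pi]
    # membership of every midpoint in every feature row (small gene sets;
    # feature count ~ 10 per gene)
    best_rank <- rep(99L, length(pi))
    best_absd <- rep(Inf, length(pi))
    best_gene <- rep(NA_character_, length(pi))
    best_d <- rep(NA_real_, length(pi))
    for (j in seq_len(nrow(fi))) {
      inside <- mids >= fi$start[j] & mids < fi$end[j]
      if (!any(inside)) next
      d <- if (fi$strand[j] == "+") mids - fi$tss[j] else fi$tss[j] - mids
      better <- inside &
        (fi$rank[j] < best_rank |
           (fi$rank[j] == best_rank &
              (abs(d) < best_absd |
                 (abs(d) == best_absd &
                    (is.na(best_gene) | fi$gene[j] < best_gene)))))
      if (any(better)) {
        best_rank[better] <- fi$rank[j]
        best_absd[better] <- abs(d)[better]
        best_gene[better] <- fi$gene[j]
        best_d[better] <- d[better]
      }
    }
    hit <- best_rank <= 5L & best_absd <= params$link_max_bp
    out$category[pi[hit]] <- .CATEGORIES[best_rank[hit]]
    out$target_gene[pi[hit]] <- best_gene[hit]
    out$tss_distance[pi[hit]] <- best_d[hit]
  }
  out
}

#' Classify a single peak
#' @param peak One-row peak data.frame.
#' @param genes Gene data.frame.
#' @param params \code{\link{annotation_params}}.
#' @return One-row annotation data.frame (see \code{\link{classify_peaks}}).
#' @export
classify_peak <- function(peak, genes, params = annotation_params()) {
  classify_peaks(peak, genes, params)
}

#' Category distribution of annotated peaks
#'
#' @param annotated Output of \code{\link{classify_peaks}}.
#' @return data.frame with one row per observed category: category,
#'   n_peaks, n_genes (distinct target genes in that category). Peak
#'   counts sum to \code{nrow(annotated)}.
#' @export
category_distribution <- function(annotated) {
  if (!nrow(annotated)) {
    return(data.frame(category = character(), n_peaks = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  cats <- unique(annotated$category)
  cats <- .CATEGORIES[.CATEGORIES %in% cats]
  data.frame(
    category = cats,
    n_peaks = vapply(cats, function(k) sum(annotated$category == k), 0L),
    n_genes = vapply(cats, function(k) {
      length(unique(stats::na.omit(
        annotated$target_gene[annotated$category == k])))
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}
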