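#' Differential-expression status from DESeq2-style columns
#'
#' A gene is \code{up} iff \code{fdr < fdr_cut} and \code{stat > stat_cut},
#' \code{down} iff \code{fdr < fdr_cut} and \code{stat < -stat_cut},
#' otherwise \code{unchanged}. All inequalities are strict, so a gene
#' sitting exactly on a boundary is unchanged.
#'
#' @param stat signed Wald-style statistic (vectorised).
#' @param fdr adjusted p-value in [0, 1].
#' @param fdr_cut,stat_cut thresholds (defaults 0.05 and 2).
#' @return character vector in \{up, down, unchanged\}.
#' @export
de_status <- function(stat, fdr, fdr_cut = 0.05, stat_cut = 2) {
  out <- rep("unchanged", length(stat))
  sig <- !is.na(fdr) & !is.na(stat) & fdr < fdr_cut
  out[sig & stat > stat_cut] <- "up"
  out[sig & stat < -stat_cut] <- "down"
  out
}

# pick sample columns by metadata; meta has columns sample, condition, day
meta_samples <- function(meta, condition = NULL, day = NULL) {
  sel <- rep(TRUE, nrow(meta))
  if (!is.null(condition)) sel <- sel & meta$condition %in% condition
  if (!is.null(day)) sel <- sel & meta$day %in% day
  meta$sample[sel]
}

#' Normalise an expression matrix to control cells at day 5
#'
#' Each gene's values are divided by the mean of its control (CON) day-5
#' replicates. Genes whose control day-5 mean is not positive cannot be
#' normalised; they are dropped and reported.
#'
#' @param expr genes x samples TPM matrix.
#' @param meta sample metadata data.frame with columns \code{sample},
#'   \code{condition} (CON/KD), \code{day}, \code{replicate}.
#' @return list with \code{matrix} (normalised) and \code{excluded}
#'   (gene ids with non-positive control day-5 mean).
#' @export
normalize_to_control_day5 <- function(expr, meta) {
  ref <- intersect(colnames(expr), meta_samples(meta, "CON", 5))
  if (!length(ref)) stop("no CON day-5 samples in the matrix")
  ref_mean <- rowMeans(expr[, ref, drop = FALSE])
  bad <- ref_mean <= 0
  list(matrix = expr[!bad, , drop = FALSE] / ref_mean[!bad],
       excluded = rownames(expr)[bad])
}

#' Two-cluster structure of putative target genes
#'
#' Agglomerative clustering (Euclidean distance on the log2-transformed
#' combined day-5 + day-7 expression vectors), tree cut at k = 2. Cluster
#' labels carry meaning: cluster I is the one with the lower mean
#' knockdown/control expression ratio (the down-regulated cluster),
#' cluster II the other.
#'
#' @param expr genes x samples TPM matrix of the putative target genes
#'   (at least 2 genes).
#' @param meta sample metadata (see
#'   \code{\link{normalize_to_control_day5}}).
#' @param linkage hclust agglomeration method (default \code{"average"}).
#' @param pseudocount added before log2 (default 1).
#' @return data.frame with \code{gene_id}, \code{cluster} ("I"/"II") and
#'   \code{order} (dendrogram leaf order).
#' @export
cluster_targets <- function(expr, meta, linkage = "average",
                            pseudocount = 1) {
  if (nrow(expr) < 2L) stop("need at least 2 genes to cluster")
  lg <- log2(expr + pseudocount)
  if (stats::sd(as.numeric(lg)) == 0)
    stop("constant expression matrix: no structure to cluster")
  hc <- stats::hclust(stats::dist(lg), method = linkage)
  lab <- stats::cutree(hc, k = 2)
  kd <- intersect(colnames(expr), meta_samples(meta, "KD"))
  con <- intersect(colnames(expr), meta_samples(meta, "CON"))
  ratio <- log2(rowMeans(expr[, kd, drop = FALSE]) + pseudocount) -
    log2(rowMeans(expr[, con, drop = FALSE]) + pseudocount)
  mr <- tapply(ratio, lab, mean)
  lower <- as.integer(names(mr)[which.min(mr)])
  data.frame(gene_id = rownames(expr),
             cluster = ifelse(lab == lower, "I", "II"),
             order = match(seq_len(nrow(expr)), hc$order))
}

#' Pearson correlation between the lncRNA and target genes, per day
#'
#' Computed over one day's samples with control and knockdown arms pooled
#' (8 samples at the full 2 x 4 design); restrict with \code{condition} to
#' use a single arm. Targets with zero variance (or a zero-variance lncRNA
#' vector) are reported as \code{NA}.
#'
#' @param expr genes x samples TPM matrix containing the lncRNA row.
#' @param meta sample metadata.
#' @param lnc_gene row name of the lncRNA.
#' @param targets row names of target genes (default: all rows but the
#'   lncRNA).
#' @param day which day's samples to use.
#' @param condition conditions to pool (default both).
#' @return named numeric vector of Pearson r in [-1, 1] (NA when
#'   undefined).
#' @export
lnc_target_correlation <- function(expr, meta, lnc_gene, targets = NULL,
                                   day, condition = c("CON", "KD")) {
  if (!lnc_gene %in% rownames(expr)) stop("lncRNA gene not in matrix")
  smp <- intersect(colnames(expr), meta_samples(meta, condition, day))
  if (length(smp) < 3L) stop("need at least 3 samples for a correlation")
  if (is.null(targets)) targets <- setdiff(rownames(expr), lnc_gene)
  x <- expr[lnc_gene, smp]
  vapply(targets, function(g) {
    y <- expr[g, smp]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
}

#' Per-target report: cluster, per-day regulation and correlation
#'
#' Joins the two-cluster structure, the DE status per day and the per-day
#' lncRNA correlation into one table per putative target gene.
#'
#' @param expr genes x samples TPM matrix (targets plus the lncRNA row).
#' @param meta sample metadata.
#' @param de data.frame with \code{gene_id}, \code{day}, \code{stat},
#'   \code{fdr}.
#' @param lnc_gene row name of the lncRNA.
#' @param fdr_cut,stat_cut thresholds for \code{\link{de_status}}.
#' @return data.frame with one row per target gene.
#' @export
target_gene_report <- function(expr, meta, de, lnc_gene,
                               fdr_cut = 0.05, stat_cut = 2) {
  targets <- setdiff(rownames(expr), lnc_gene)
  cl <- cluster_targets(expr[targets, , drop = FALSE], meta)
  out <- data.frame(gene_id = targets,
                    cluster = cl$cluster[match(targets, cl$gene_id)])
  for (d in sort(unique(meta$day))) {
    dd <- de[de$day == d, , drop = FALSE]
    idx <- match(targets, dd$gene_id)
    out[[paste0("regulation_day", d)]] <-
      ifelse(is.na(idx), "unchanged",
             de_status(dd$stat[idx], dd$fdr[idx], fdr_cut, stat_cut))
    out[[paste0("r_day", d)]] <-
      lnc_target_correlation(expr, meta, lnc_gene, targets, day = d)
  }
  out
}

#' Candidate lncRNA screen: tissue restriction, dynamics, conservation
#'
#' A transcript passes when (1) it is expressed above \code{expr_threshold}
#' in at least one neural tissue and below it in every non-neural tissue,
#' (2) a two-sided paired t test across before/after differentiation pairs
#' rejects at \code{alpha} after Benjamini-Hochberg correction across
#' transcripts, and (3) its conservation flag is set. The direction of a
#' passing candidate is the sign of its mean after-minus-before change.
#'
#' @param tissue_expr transcripts x tissues expression matrix.
#' @param neural named logical vector over the tissue columns (TRUE =
#'   neural); every column must be labelled.
#' @param before,after transcripts x cell-type matrices of paired
#'   expression values before and after differentiation.
#' @param conserved logical vector per transcript.
#' @param alpha BH-adjusted significance level.
#' @param expr_threshold "expressed" cutoff on the tissue matrix.
#' @return data.frame per transcript with the three criterion columns,
#'   \code{p}, \code{padj}, \code{pass} and \code{direction}
#'   (increase/decrease, NA for non-passing).
#' @export
screen_candidates <- function(tissue_expr, neural, before, after, conserved,
                              alpha = 0.05, expr_threshold = 1) {
  if (is.null(names(neural)) ||
      !all(colnames(tissue_expr) %in% names(neural)))
    stop("every tissue column needs a neural/non-neural label")
  neural <- neural[colnames(tissue_expr)]
  if (anyNA(neural)) stop("missing tissue labels")
  n_ok <- rowSums(tissue_expr[, neural, drop = FALSE] > expr_threshold) >= 1L
  nn_ok <- rowSums(tissue_expr[, !neural, drop = FALSE] >=
                     expr_threshold) == 0L
  neural_only <- n_ok & nn_ok
  p <- vapply(seq_len(nrow(before)), function(i) {
    d <- after[i, ] - before[i, ]
    # numerically constant differences: the t statistic is degenerate,
    # so decide directly from the mean shift
    if (length(d) < 2L ||
        stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1e-12))
      return(if (mean(d) == 0) 1 else 0)
    stats::t.test(after[i, ], before[i, ], paired = TRUE)$p.value
  }, 0)
  padj <- stats::p.adjust(p, method = "BH")
  delta <- rowMeans(after) - rowMeans(before)
  pass <- neural_only & padj < alpha & conserved
  data.frame(transcript = rownames(tissue_expr),
             neural_only = neural_only, p = p, padj = padj,
             conserved = conserved, pass = pass,
             direction = ifelse(pass,
                                ifelse(delta > 0, "increase", "decrease"),
                                NA_character_))
}
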