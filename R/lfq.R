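# run code under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Filter and log-transform a label-free quantification matrix
#'
#' Proteins flagged as reverse hits, contaminants or identified only by a
#' modification site are dropped; intensities are log2-transformed (zeros
#' count as missing); only protein groups quantified in all five replicates
#' of at least one condition are kept. A protein fully quantified in one
#' condition and never in the other is tagged \code{exclusive} -- these are
#' the candidate condition-specific interactors that imputation will make
#' testable.
#'
#' @param intensity proteins x samples matrix of raw intensities (NA or 0
#'   = missing).
#' @param condition character/factor per column with exactly two levels,
#'   five samples each (the 5 vs 5 design is assumed and enforced).
#' @param flags optional data.frame with logical columns \code{reverse},
#'   \code{contaminant}, \code{site} per protein.
#' @return list with \code{log2} (filtered matrix), \code{condition},
#'   \code{exclusive} (named logical) and \code{dropped_flagged} (ids).
#' @export
lfq_preprocess <- function(intensity, condition, flags = NULL) {
  condition <- as.character(condition)
  tab <- table(condition)
  if (length(tab) != 2L || any(tab != 5L))
    stop("design must be 5 vs 5 (got ",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  dropped <- character()
  if (!is.null(flags)) {
    bad <- rowSums(sapply(c("reverse", "contaminant", "site"), function(f)
      if (f %in% names(flags)) flags[[f]] else FALSE)) > 0
    dropped <- rownames(intensity)[bad]
    intensity <- intensity[!bad, , drop = FALSE]
  }
  m <- intensity
  m[!is.na(m) & m <= 0] <- NA
  m <- log2(m)
  lv <- unique(condition)
  n1 <- rowSums(!is.na(m[, condition == lv[1L], drop = FALSE]))
  n2 <- rowSums(!is.na(m[, condition == lv[2L], drop = FALSE]))
  keep <- n1 == 5L | n2 == 5L
  m <- m[keep, , drop = FALSE]
  exclusive <- (n1[keep] == 5L & n2[keep] == 0L) |
    (n2[keep] == 5L & n1[keep] == 0L)
  names(exclusive) <- rownames(m)
  list(log2 = m, condition = condition, exclusive = exclusive,
       dropped_flagged = dropped)
}

#' Impute missing log2 intensities from a down-shifted Gaussian
#'
#' Each missing cell is drawn independently from
#' \eqn{N(\mu_c - d\,\sigma_c, (w\,\sigma_c)^2)} where \eqn{\mu_c},
#' \eqn{\sigma_c} are the mean and SD of the \emph{observed} values of its
#' column -- the standard width-and-down-shift imputation for
#' left-censored LFQ missingness. Observed cells are never touched.
#'
#' @param m log2 matrix with NAs.
#' @param d down-shift in column SDs (default 2).
#' @param w width in column SDs (default 0.2).
#' @param seed integer seed for reproducibility (global RNG state is
#'   restored afterwards).
#' @return complete matrix of the same shape.
#' @export
lfq_impute <- function(m, d = 2, w = 0.2, seed = NULL) {
  nobs <- colSums(!is.na(m))
  if (any(nobs < 2L))
    stop("column(s) with fewer than 2 observed values: cannot impute")
  mu <- colMeans(m, na.rm = TRUE)
  sdev <- apply(m, 2, stats::sd, na.rm = TRUE)
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- which(is.na(m[, j]))
      if (length(miss))
        m[miss, j] <- stats::rnorm(length(miss), mu[j] - d * sdev[j],
                                   w * sdev[j])
    }
    m
  })
}

# core s0 statistic for group matrices (proteins x samples), vectorised
d_s0_stat <- function(A, B, s0) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  sp <- sqrt((ssA + ssB) / (nA + nB - 2))
  (mA - mB) / (sp * sqrt(1 / nA + 1 / nB) + s0)
}

#' SAM-style s0-moderated two-sample test
#'
#' The statistic adds a constant \code{s0} to the denominator of the pooled
#' two-sample t, damping significance of tiny effects with tiny variance:
#' \deqn{d_{s0} = (\bar A - \bar B) / (s_p \sqrt{1/n_A + 1/n_B} + s_0).}
#' For \code{s0 = 0} the two-sided p-value is exactly Student's pooled t
#' with \eqn{n_A + n_B - 2} df; for \code{s0 > 0} the p-value comes from
#' the exhaustive permutation distribution of \eqn{d_{s0}} over all
#' re-assignments of the pooled values into groups of the original sizes.
#'
#' @param a,b numeric vectors (at least 2 values each).
#' @param s0 the fudge constant (>= 0).
#' @return list with \code{d} (the statistic) and \code{p} (two-sided).
#' @export
s0_t_test <- function(a, b, s0 = 0.1) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  d <- d_s0_stat(matrix(a, 1L), matrix(b, 1L), s0)
  if (s0 == 0) {
    if (!is.finite(d)) stop("zero pooled variance with s0 = 0: undefined")
    p <- 2 * stats::pt(-abs(d), df = length(a) + length(b) - 2)
  } else {
    pool <- c(a, b)
    idx <- utils::combn(length(pool), length(a))
    dn <- apply(idx, 2, function(i)
      d_s0_stat(matrix(pool[i], 1L), matrix(pool[-i], 1L), s0))
    p <- mean(abs(dn) >= abs(d) - 1e-12)
  }
  list(d = unname(d), p = unname(p))
}

#' Permutation-based FDR for a 5 vs 5 LFQ design
#'
#' Observed \eqn{d_{s0}} per protein is compared with the pooled null
#' distribution over all \eqn{\binom{10}{5} = 252} balanced label
#' re-assignments (126 distinct up to group swap; enumerating all 252 is
#' equivalent for the two-sided statistic and needs no sampling, so the
#' estimate is deterministic). The significance cut is the smallest
#' threshold on \eqn{|d_{s0}|} at which the estimated FDR -- the median
#' across permutations of the number of null exceedances, divided by the
#' number of observed calls -- stays at or below \code{alpha}. Per-protein
#' p-values are taken from the pooled null. For volcano display the
#' significance boundary is sampled as (log2 ratio, -log10 p) pairs on both
#' sides.
#'
#' @param m complete (imputed) log2 matrix, proteins x 10 samples.
#' @param condition two-level labels per column, 5 each.
#' @param numerator,denominator condition levels defining the reported
#'   ratio \code{log2(numerator/denominator)}.
#' @param s0 fudge constant (default 0.1).
#' @param alpha target FDR (default 0.05).
#' @return data.frame per protein: \code{protein}, \code{log2_ratio},
#'   \code{d}, \code{pvalue}, \code{neg_log10_p}, \code{significant}.
#'   Attributes \code{d_cut} (the chosen threshold, Inf if none) and
#'   \code{curve} (boundary samples).
#' @export
permutation_fdr <- function(m, condition, numerator = NULL,
                            denominator = NULL, s0 = 0.1, alpha = 0.05) {
  condition <- as.character(condition)
  lv <- unique(condition)
  tab <- table(condition)
  if (length(lv) != 2L || any(tab != 5L))
    stop("permutation FDR requires a balanced 5 vs 5 design")
  if (is.null(numerator)) numerator <- lv[1L]
  if (is.null(denominator)) denominator <- setdiff(lv, numerator)[1L]
  A <- m[, condition == numerator, drop = FALSE]
  B <- m[, condition == denominator, drop = FALSE]
  d_obs <- d_s0_stat(A, B, s0)
  ratio <- rowMeans(A) - rowMeans(B)
  pool <- cbind(A, B)
  idx <- utils::combn(10L, 5L)                       # 252 assignments
  d_null <- apply(idx, 2, function(i)
    d_s0_stat(pool[, i, drop = FALSE], pool[, -i, drop = FALSE], s0))
  d_null <- matrix(d_null, nrow = nrow(m))           # proteins x perms
  abs_null <- abs(d_null)
  abs_obs <- abs(d_obs)
  # pooled permutation p-value per protein
  ord <- sort(abs_null)
  pvalue <- (length(ord) - findInterval(abs_obs - 1e-12, ord)) / length(ord)
  pvalue <- pmax(pvalue, 1 / length(ord))
  # FDR-controlling cut on |d|
  cuts <- sort(unique(abs_obs), decreasing = TRUE)
  d_cut <- Inf
  for (cc in cuts) {
    calls <- sum(abs_obs >= cc)
    false_calls <- apply(abs_null >= cc, 2, sum)
    fdr <- stats::median(false_calls) / max(1L, calls)
    if (fdr <= alpha) d_cut <- cc else break
  }
  res <- data.frame(protein = rownames(m), log2_ratio = ratio, d = d_obs,
                    pvalue = pvalue, neg_log10_p = -log10(pvalue),
                    significant = abs_obs >= d_cut)
  rownames(res) <- NULL
  attr(res, "d_cut") <- d_cut
  attr(res, "curve") <- fdr_curve(d_cut, s0, df = 8L)
  res
}

# sample the volcano-plot significance boundary |d_s0| = d_cut as
# (log2 ratio, -log10 p) pairs; p mapped through the t distribution
fdr_curve <- function(d_cut, s0, df, n = 200L) {
  if (!is.finite(d_cut))
    return(data.frame(log2_ratio = numeric(), neg_log10_p = numeric()))
  fc <- seq(s0 * d_cut * 1.001, s0 * d_cut + 4, length.out = n)
  se <- fc / d_cut - s0
  t <- fc / se
  p <- 2 * stats::pt(-abs(t), df)
  rbind(data.frame(log2_ratio = -rev(fc), neg_log10_p = -log10(rev(p))),
        data.frame(log2_ratio = fc, neg_log10_p = -log10(p)))
}

#' Threshold classification of enrichment records
#'
#' A protein is enriched toward the ratio's \emph{denominator} when
#' \code{log2_ratio < -log2(fc_threshold)} and \code{p < p_threshold}, and
#' toward the \emph{numerator} for the mirrored ratio condition. With the
#' conventional ratio log2(mutant/full-length), "denominator" means
#' enriched by the full-length RNA.
#'
#' @param log2_ratio numeric vector.
#' @param neg_log10_p \eqn{-\log_{10}} p-values (alternatively supply
#'   \code{p}).
#' @param p raw p-values (used if \code{neg_log10_p} is missing).
#' @param fc_threshold fold-change gate (default 2).
#' @param p_threshold p-value gate (default 0.002).
#' @return character vector in \{denominator, numerator, none\}.
#' @export
classify_enrichment <- function(log2_ratio, neg_log10_p = NULL, p = NULL,
                                fc_threshold = 2, p_threshold = 0.002) {
  if (is.null(neg_log10_p)) {
    if (is.null(p)) stop("supply neg_log10_p or p")
    neg_log10_p <- -log10(p)
  }
  psig <- neg_log10_p > -log10(p_threshold)
  lfc <- log2(fc_threshold)
  out <- rep("none", length(log2_ratio))
  out[psig & log2_ratio < -lfc] <- "denominator"
  out[psig & log2_ratio > lfc] <- "numerator"
  out
}

#' Count enriched proteins per nuclear compartment
#'
#' Counts are taken over the records enriched toward the denominator
#' condition (the full-length RNA in the canonical mut/fl ratio).
#' Unannotated records count as \code{none}.
#'
#' @param records data.frame with \code{log2_ratio}, \code{neg_log10_p}
#'   and \code{compartment} columns.
#' @param fc_threshold,p_threshold gates for
#'   \code{\link{classify_enrichment}}.
#' @return named integer vector of counts per compartment.
#' @export
compartment_counts <- function(records, fc_threshold = 2,
                               p_threshold = 0.002) {
  cls <- classify_enrichment(records$log2_ratio, records$neg_log10_p,
                             fc_threshold = fc_threshold,
                             p_threshold = p_threshold)
  comp <- records$compartment
  comp[is.na(comp) | !nzchar(comp)] <- "none"
  tab <- table(comp[cls == "denominator"])
  out <- stats::setNames(as.integer(tab), names(tab))
  out
}

#' One-sample, one-tailed t test with Bonferroni adjustment
#'
#' @param values numeric vector (>= 2 values, non-zero variance).
#' @param mu0 null mean.
#' @param m number of comparisons for Bonferroni (default 1).
#' @param alternative \code{"greater"} (default) or \code{"less"}.
#' @return list with \code{t}, \code{p} (raw) and \code{p_adjusted}
#'   (\code{min(1, m * p)}).
#' @export
one_tailed_t_bonferroni <- function(values, mu0 = 0, m = 1L,
                                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values) < 2L) stop("need >= 2 values")
  if (stats::sd(values) == 0) stop("zero variance: t undefined")
  n <- length(values)
  t <- (mean(values) - mu0) / (stats::sd(values) / sqrt(n))
  p <- if (alternative == "greater") stats::pt(t, n - 1, lower.tail = FALSE)
  else stats::pt(t, n - 1)
  list(t = t, p = p, p_adjusted = min(1, m * p))
}

#' Load the packaged nuclear-interactor table
#'
#' A 48-row table of nuclear proteins enriched by affinity purification of
#' a full-length lncRNA versus a 5'-truncated mutant, with precomputed
#' \eqn{-\log_{10}} p-values and log2(mut/fl) ratios, an
#' exclusive-detection flag and nuclear-compartment annotations. Used as a
#' worked example and regression fixture for the enrichment
#' classification.
#'
#' @param path TSV path; defaults to the packaged copy.
#' @return data.frame with \code{uniprot}, \code{gene_name},
#'   \code{neg_log10_p}, \code{log2_ratio}, \code{exclusive},
#'   \code{compartment}.
#' @export
read_interactor_table <- function(path = system.file(
  "extdata", "nuclear_interactors.tsv", package = "chirptools")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$exclusive <- df$exclusive == "yes"
  df$compartment[is.na(df$compartment) | !nzchar(df$compartment)] <- "none"
  df
}
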