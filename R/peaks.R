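# cumulative signal of a segment list up to position p (0-based), vectorized
track_cum <- function(seg, p) {
  if (!nrow(seg)) return(numeric(length(p)))
  w <- seg$end - seg$start
  cum_before <- c(0, cumsum(as.numeric(w) * seg$value))
  idx <- findInterval(p, seg$start)
  out <- cum_before[idx + 1L]
  inpart <- idx > 0L
  out[inpart] <- cum_before[idx[inpart]] +
    seg$value[idx[inpart]] *
    pmax(0, pmin(p[inpart], seg$end[idx[inpart]]) - seg$start[idx[inpart]])
  out
}

#' Call candidate peaks against a local Poisson background
#'
#' A deliberately simple stand-in for a full peak caller: the tag-density
#' track is scanned in sliding windows and a window is a candidate when its
#' summed signal exceeds a Poisson background at \code{p_threshold}. The
#' background rate for a window is the largest of the genome-wide mean rate
#' and the mean rates in its 5-kb and 10-kb flanks (the dynamic-lambda idea
#' of count-based callers), so broad local enrichment does not inflate
#' calls. Overlapping candidate windows are merged, the merged interval is
#' trimmed to the covered span, the summit is the leftmost maximum of the
#' signal, and peaks shorter than \code{min_length} are discarded.
#' Externally called peaks (narrowPeak) can be supplied to downstream steps
#' instead; nothing else in the pipeline depends on this caller.
#'
#' @param track a \code{CoverageTrack} (tag density, counts per base).
#' @param window window width in bp.
#' @param p_threshold Poisson upper-tail threshold per window.
#' @param min_length minimum retained peak length in bp.
#' @param step window step in bp (default half a window).
#' @return data.frame of peaks: \code{chrom}, \code{start}, \code{end},
#'   \code{summit}, \code{score} (\eqn{-10 \log_{10} p}), \code{pvalue}.
#' @export
call_peaks <- function(track, window = 200L, p_threshold = 1e-5,
                       min_length = 100L, step = window %/% 2L) {
  stopifnot(inherits(track, "CoverageTrack"))
  total <- track_total(track)
  glen <- sum(as.numeric(track$assembly$seqlengths))
  if (total <= 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      score = numeric(), pvalue = numeric()))
  grate <- total / glen
  out <- list()
  for (ch in names(track$assembly$seqlengths)) {
    L <- track$assembly$seqlengths[[ch]]
    seg <- track$segments[track$segments$chrom == ch, , drop = FALSE]
    if (!nrow(seg) || L < window) next
    starts <- seq.int(0L, L - window, by = max(1L, step))
    ends <- starts + window
    x <- track_cum(seg, ends) - track_cum(seg, starts)
    flank_rate <- function(size) {
      lo <- pmax(0L, starts - size); hi <- pmin(L, ends + size)
      fsum <- (track_cum(seg, starts) - track_cum(seg, lo)) +
        (track_cum(seg, hi) - track_cum(seg, ends))
      fw <- (starts - lo) + (hi - ends)
      ifelse(fw > 0, fsum / fw, 0)
    }
    lambda <- window * pmax(grate, flank_rate(5000L), flank_rate(10000L))
    p <- stats::ppois(ceiling(x) - 1, lambda, lower.tail = FALSE)
    sig <- which(p < p_threshold & x > 0)
    if (!length(sig)) next
    # merge overlapping/touching significant windows
    ss <- starts[sig]; se <- ends[sig]; sp <- p[sig]
    grp <- cumsum(c(TRUE, ss[-1L] > cummax(se)[-length(se)]))
    for (g in unique(grp)) {
      i <- grp == g
      a <- min(ss[i]); b <- max(se[i])
      # trim to the covered span inside the merged window union
      inseg <- seg[seg$end > a & seg$start < b, , drop = FALSE]
      if (nrow(inseg)) {
        a <- max(a, min(inseg$start)); b <- min(b, max(inseg$end))
      }
      if (b - a < min_length) next
      pk <- min(sp[i])
      sm <- region_max(track, ch, a, b)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = a, end = b, summit = sm$pos,
        score = -10 * log10(max(pk, 1e-300)), pvalue = pk)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      score = numeric(), pvalue = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pair even-probe and odd-probe peaks of one replicate
#'
#' Two peaks form a pair when their intervals overlap by at least 1 bp and
#' their summits are within \code{max_summit_distance} of each other.
#' Matching is greedy by smallest summit distance and each peak enters at
#' most one pair, so the result is deterministic and order-independent.
#' Setting \code{sense = "min"} flips the summit rule to \emph{at least}
#' the given separation (the literal reading of a minimum distance); the
#' default \code{"max"} treats the 200-bp figure as the largest tolerated
#' separation between concordant probe-set summits.
#'
#' @param peaks_even,peaks_odd peak data.frames (same replicate); summits
#'   must be present (recompute unknown summits with
#'   \code{\link{region_max}} first).
#' @param max_summit_distance allowed even/odd summit separation in bp.
#' @param sense \code{"max"} (default) or \code{"min"}, see above.
#' @return data.frame of pairs with footprint columns \code{chrom},
#'   \code{start}, \code{end} (union of the two peaks),
#'   \code{summit_even}, \code{summit_odd}, \code{summit_distance}, and the
#'   row indices \code{idx_even}, \code{idx_odd} of the source peaks.
#' @export
pair_even_odd <- function(peaks_even, peaks_odd, max_summit_distance = 200L,
                          sense = c("max", "min")) {
  sense <- match.arg(sense)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), summit_even = integer(),
                      summit_odd = integer(), summit_distance = integer(),
                      idx_even = integer(), idx_odd = integer())
  if (!nrow(peaks_even) || !nrow(peaks_odd)) return(empty)
  if (anyNA(peaks_even$summit) || anyNA(peaks_odd$summit))
    stop("peaks with unknown summits: recompute summits before pairing")
  ge <- GenomicRanges::GRanges(peaks_even$chrom,
                               IRanges::IRanges(peaks_even$start + 1L,
                                                peaks_even$end))
  go <- GenomicRanges::GRanges(peaks_odd$chrom,
                               IRanges::IRanges(peaks_odd$start + 1L,
                                                peaks_odd$end))
  hits <- GenomicRanges::findOverlaps(ge, go)
  if (!length(hits)) return(empty)
  ie <- S4Vectors::queryHits(hits); io <- S4Vectors::subjectHits(hits)
  d <- abs(peaks_even$summit[ie] - peaks_odd$summit[io])
  ok <- if (sense == "max") d <= max_summit_distance else d >= max_summit_distance
  ie <- ie[ok]; io <- io[ok]; d <- d[ok]
  if (!length(ie)) return(empty)
  o <- order(d, ie, io)
  used_e <- logical(nrow(peaks_even)); used_o <- logical(nrow(peaks_odd))
  keep <- logical(length(o))
  for (k in o) {
    if (used_e[ie[k]] || used_o[io[k]]) next
    used_e[ie[k]] <- TRUE; used_o[io[k]] <- TRUE; keep[k] <- TRUE
  }
  ie <- ie[keep]; io <- io[keep]; d <- d[keep]
  res <- data.frame(
    chrom = peaks_even$chrom[ie],
    start = pmin(peaks_even$start[ie], peaks_odd$start[io]),
    end = pmax(peaks_even$end[ie], peaks_odd$end[io]),
    summit_even = peaks_even$summit[ie],
    summit_odd = peaks_odd$summit[io],
    summit_distance = d, idx_even = ie, idx_odd = io)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# lower median: for even n the lower of the two central order statistics
lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Triplicate consensus over even/odd peak pairs
#'
#' A consensus site is emitted where one even/odd pair footprint from
#' \emph{each} of the three replicates mutually overlaps by at least 1 bp
#' (the three-of-three rule). The site interval is the union of the three
#' footprints (contiguous because they mutually overlap, anchored on their
#' common intersection), the representative summit is the median of the six
#' probe-set summits (ties to the lower coordinate), and each footprint
#' supports at most one site (greedy matching by largest common
#' intersection, deterministic order).
#'
#' @param pairs_rep1,pairs_rep2,pairs_rep3 pair data.frames from
#'   \code{\link{pair_even_odd}}, one per replicate.
#' @return data.frame of consensus sites: \code{chrom}, \code{start},
#'   \code{end}, \code{summit}, \code{support} (always 3) and
#'   \code{summits} (comma-separated six summit positions,
#'   rep1 even/odd, rep2 even/odd, rep3 even/odd).
#' @export
replicate_consensus <- function(pairs_rep1, pairs_rep2, pairs_rep3) {
  if (missing(pairs_rep2) || missing(pairs_rep3))
    stop("three replicate pair lists are required")
  reps <- list(pairs_rep1, pairs_rep2, pairs_rep3)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      support = integer(), summits = character())
  if (any(!vapply(reps, nrow, 0L))) return(empty)
  ov <- function(a1, a2, b1, b2) pmin(a2, b2) - pmax(a1, b1)  # bp overlap
  used2 <- logical(nrow(pairs_rep2)); used3 <- logical(nrow(pairs_rep3))
  out <- list()
  o1 <- order(pairs_rep1$chrom, pairs_rep1$start)
  for (i in o1) {
    a <- pairs_rep1[i, ]
    c2 <- which(!used2 & pairs_rep2$chrom == a$chrom &
                  ov(a$start, a$end, pairs_rep2$start, pairs_rep2$end) > 0)
    c3 <- which(!used3 & pairs_rep3$chrom == a$chrom &
                  ov(a$start, a$end, pairs_rep3$start, pairs_rep3$end) > 0)
    if (!length(c2) || !length(c3)) next
    # best (b, c): maximal width of the triple intersection, ties to the
    # lowest indices
    best <- NULL; best_w <- -Inf
    for (j in c2) for (k in c3) {
      w <- min(a$end, pairs_rep2$end[j], pairs_rep3$end[k]) -
        max(a$start, pairs_rep2$start[j], pairs_rep3$start[k])
      if (w > 0 &&
          ov(pairs_rep2$start[j], pairs_rep2$end[j],
             pairs_rep3$start[k], pairs_rep3$end[k]) > 0 &&
          w > best_w) {
        best <- c(j, k); best_w <- w
      }
    }
    if (is.null(best)) next
    j <- best[1L]; k <- best[2L]
    used2[j] <- TRUE; used3[k] <- TRUE
    summits <- c(a$summit_even, a$summit_odd,
                 pairs_rep2$summit_even[j], pairs_rep2$summit_odd[j],
                 pairs_rep3$summit_even[k], pairs_rep3$summit_odd[k])
    out[[length(out) + 1L]] <- data.frame(
      chrom = a$chrom,
      start = min(a$start, pairs_rep2$start[j], pairs_rep3$start[k]),
      end = max(a$end, pairs_rep2$end[j], pairs_rep3$end[k]),
      summit = lower_median(summits), support = 3L,
      summits = paste(summits, collapse = ","))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
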