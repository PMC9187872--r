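#' Coverage track over a genome assembly
#'
#' Piecewise-constant, non-negative per-base signal, stored as sorted
#' disjoint segments in 0-based half-open coordinates. Bases not covered by
#' any segment have value 0 implicitly; zero-valued segments are dropped and
#' touching segments of equal value are coalesced, so the representation is
#' canonical.
#'
#' @param assembly a \code{GenomeAssembly}.
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{value}. Overlapping input segments are a validation
#'   error (a bedGraph is a function, not a pile-up).
#' @return an object of class \code{CoverageTrack}.
#' @export
coverage_track <- function(assembly, segments) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  segments <- as.data.frame(segments)
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(segments)))
    stop("segments must have columns chrom, start, end, value")
  segments$chrom <- as.character(segments$chrom)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$value <- as.numeric(segments$value)
  if (nrow(segments)) {
    if (any(!is.finite(segments$value)) || any(segments$value < 0))
      stop("coverage values must be finite and non-negative")
    check_bounds(segments$chrom, segments$start, segments$end, assembly,
                 what = "coverage segment")
    o <- order(segments$chrom, segments$start)
    segments <- segments[o, , drop = FALSE]
    same <- segments$chrom[-1L] == segments$chrom[-nrow(segments)]
    if (nrow(segments) > 1L &&
        any(same & segments$start[-1L] < segments$end[-nrow(segments)]))
      stop("overlapping segments in coverage input")
    segments <- segments[segments$value > 0, , drop = FALSE]
    segments <- coalesce_segments(segments)
  }
  rownames(segments) <- NULL
  structure(list(assembly = assembly, segments = segments),
            class = "CoverageTrack")
}

# merge touching runs of equal value (already sorted, disjoint, nonzero)
coalesce_segments <- function(seg) {
  n <- nrow(seg)
  if (n < 2L) return(seg)
  joinable <- seg$chrom[-1L] == seg$chrom[-n] &
    seg$start[-1L] == seg$end[-n] &
    seg$value[-1L] == seg$value[-n]
  grp <- cumsum(c(TRUE, !joinable))
  first <- !duplicated(grp)
  out <- seg[first, , drop = FALSE]
  out$end <- tapply(seg$end, grp, max)[unique(grp)]
  out$end <- as.integer(out$end)
  rownames(out) <- NULL
  out
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", nrow(x$segments), "segment(s) on",
      length(unique(x$segments$chrom)), "chromosome(s); total signal",
      format(track_total(x)), "\n")
  invisible(x)
}

# step-function evaluation: value of sorted disjoint segments at points p
step_eval <- function(start, end, value, p) {
  if (!length(start)) return(numeric(length(p)))
  idx <- findInterval(p, start)
  out <- numeric(length(p))
  hit <- idx > 0L
  hit[hit] <- p[hit] < end[idx[hit]]
  out[hit] <- value[idx[hit]]
  out
}

#' Per-base values of a track at given positions
#'
#' Mainly used by brute-force oracles in the test-suite; positions are
#' 0-based.
#' @param track a \code{CoverageTrack}.
#' @param chrom chromosome name.
#' @param positions integer vector of 0-based positions.
#' @return numeric vector of values (0 where uncovered).
#' @export
track_values <- function(track, chrom, positions) {
  seg <- track$segments[track$segments$chrom == chrom, , drop = FALSE]
  step_eval(seg$start, seg$end, seg$value, positions)
}

#' Total signal of a track (sum of value times segment width)
#' @param track a \code{CoverageTrack}.
#' @export
track_total <- function(track) {
  with(track$segments, sum(value * (end - start)))
}

#' Merge even and odd probe-set coverage by the per-base minimum
#'
#' The "take-lower" merge: at every base the output equals
#' \code{min(even(b), odd(b))}. Signal present in only one probe set is
#' thereby suppressed, which is the point -- enrichment supported by a
#' single probe set is more likely a probe artifact than genuine RNA
#' occupancy. A region covered in one track and uncovered in the other
#' yields 0. Optional per-track scale factors allow depth adjustment before
#' merging (the default, 1, merges raw tracks).
#'
#' @param track_even,track_odd \code{CoverageTrack}s on the same assembly.
#' @param scale_even,scale_odd multiplicative factors applied before the
#'   minimum is taken.
#' @return a \code{CoverageTrack} in canonical (coalesced) form.
#' @export
take_lower_merge <- function(track_even, track_odd,
                             scale_even = 1, scale_odd = 1) {
  stopifnot(inherits(track_even, "CoverageTrack"),
            inherits(track_odd, "CoverageTrack"))
  if (!identical(track_even$assembly$seqlengths,
                 track_odd$assembly$seqlengths))
    stop("tracks are on different assemblies")
  stopifnot(scale_even > 0, scale_odd > 0)
  chroms <- sort(unique(c(track_even$segments$chrom,
                          track_odd$segments$chrom)))
  pieces <- lapply(chroms, function(ch) {
    a <- track_even$segments[track_even$segments$chrom == ch, , drop = FALSE]
    b <- track_odd$segments[track_odd$segments$chrom == ch, , drop = FALSE]
    if (!nrow(a) || !nrow(b)) return(NULL)  # min with implicit zero is zero
    bounds <- sort(unique(c(a$start, a$end, b$start, b$end)))
    lo <- bounds[-length(bounds)]
    hi <- bounds[-1L]
    v <- pmin(scale_even * step_eval(a$start, a$end, a$value, lo),
              scale_odd * step_eval(b$start, b$end, b$value, lo))
    keep <- v > 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = lo[keep], end = hi[keep], value = v[keep])
  })
  seg <- do.call(rbind, pieces)
  if (is.null(seg))
    seg <- data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
  coverage_track(track_even$assembly, seg)
}

#' Leftmost position of maximal coverage inside an interval
#'
#' Used to localise peak summits. Ties are broken to the lowest coordinate
#' so summits are deterministic.
#'
#' @param track a \code{CoverageTrack}.
#' @param chrom,start,end the query interval (0-based half-open, non-empty).
#' @return list with elements \code{pos} (0-based) and \code{value}.
#' @export
region_max <- function(track, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  check_bounds(chrom, start, end, track$assembly, what = "query interval")
  seg <- track$segments[track$segments$chrom == chrom, , drop = FALSE]
  # candidate positions: interval start plus every breakpoint falling inside
  cand <- sort(unique(c(start,
                        seg$start[seg$start > start & seg$start < end],
                        seg$end[seg$end > start & seg$end < end])))
  v <- step_eval(seg$start, seg$end, seg$value, cand)
  i <- which.max(v)  # which.max returns the first (leftmost) maximum
  list(pos = cand[i], value = v[i])
}
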