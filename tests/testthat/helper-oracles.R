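# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute force: per-base expansion,
# exhaustive enumeration, closed forms -- never the code paths under test.

# random coverage track: n disjoint segments with integer-ish values
rand_track <- function(assembly, n = 30L, max_value = 20) {
  segs <- lapply(names(assembly$seqlengths), function(ch) {
    L <- assembly$seqlengths[[ch]]
    k <- max(1L, n %/% length(assembly$seqlengths))
    bounds <- sort(sample.int(L - 1L, 2L * k))
    data.frame(chrom = ch,
               start = bounds[seq(1L, length(bounds), 2L)],
               end = bounds[seq(2L, length(bounds), 2L)],
               value = round(stats::runif(k, 0, max_value), 3))
  })
  coverage_track(assembly, do.call(rbind, segs))
}

# per-base minimum oracle for the take-lower merge
per_base_min <- function(a, b, chrom, L) {
  pos <- 0:(L - 1L)
  pmin(track_values(a, chrom, pos), track_values(b, chrom, pos))
}

# exhaustive probe p-value oracle: enumerate all 4^L words over the
# discretised per-column integer scores, return function(k) = P(sum >= k)
enum_tail <- function(matrix, granularity) {
  k <- round(matrix$scores / granularity)
  L <- matrix$length
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  ks <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(L)) {
    ks <- ks + k[words[, j], j]
    pr <- pr * matrix$background[words[, j]]
  }
  function(kq) sum(pr[ks >= kq])
}

# does any interval of `set` overlap interval i of `q` (0-based half-open)?
overlaps_any <- function(set, chrom, start, end) {
  any(set$chrom == chrom & set$start < end & set$end > start)
}

tiny_assembly <- function(L = 10000L, n_chrom = 1L, with_seq = FALSE) {
  nm <- paste0("chr", seq_len(n_chrom))
  sl <- stats::setNames(rep(L, n_chrom), nm)
  if (!with_seq) return(genome_assembly(sl))
  seqs <- Biostrings::DNAStringSet(vapply(nm, function(x)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), ""))
  names(seqs) <- nm
  genome_assembly(sl, seqs)
}

# a rectangular coverage spike on an otherwise flat background
spike_track <- function(assembly, bg = 1, spikes = NULL) {
  ch <- names(assembly$seqlengths)[1L]
  L <- assembly$seqlengths[[1L]]
  seg <- data.frame(chrom = ch, start = 0L, end = L, value = bg)
  if (!is.null(spikes)) {
    pieces <- list()
    pos <- 0L
    for (i in seq_len(nrow(spikes))) {
      if (spikes$start[i] > pos)
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = spikes$start[i], value = bg)
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch, start = spikes$start[i], end = spikes$end[i],
        value = spikes$value[i])
      pos <- spikes$end[i]
    }
    if (pos < L)
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = L, value = bg)
    seg <- do.call(rbind, pieces)
  }
  coverage_track(assembly, seg)
}

# minimal sample metadata for the 2x2x4 knockdown design
toy_meta <- function() {
  meta <- expand.grid(replicate = 1:4, condition = c("CON", "KD"),
                      day = c(5L, 7L), stringsAsFactors = FALSE)
  meta$sample <- with(meta, paste0(condition, "_d", day, "_r", replicate))
  meta
}
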