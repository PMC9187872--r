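DNA_BASES <- c("A", "C", "G", "T")

#' Build a log-odds scoring matrix from one probe oligo
#'
#' Column frequencies are the literal probe base smoothed with a
#' pseudo-frequency towards the background:
#' \code{(1 - pseudo) * indicator(probe base) + pseudo * background}. Scores
#' are \code{log2(freq / background)} in bits, so a perfect match under a
#' uniform background approaches 2 bits per position as \code{pseudo} goes
#' to 0.
#'
#' @param probe DNA string over A/C/G/T (an N is an error; degenerate
#'   probes are not modelled).
#' @param background named base probabilities (A, C, G, T), strictly
#'   positive, summing to 1. Default uniform.
#' @param pseudo pseudo-frequency in (0, 0.5).
#' @param name probe name for reporting.
#' @return an object of class \code{ProbeMatrix} with elements
#'   \code{name}, \code{length}, \code{freqs} (4 x L), \code{scores}
#'   (4 x L, bits), \code{background}.
#' @export
build_probe_matrix <- function(probe, background = NULL, pseudo = 0.01,
                               name = "probe") {
  probe <- toupper(probe)
  bases <- strsplit(probe, "")[[1L]]
  if (length(bases) < 4L) stop("probe must be at least 4 nt")
  if (any(!bases %in% DNA_BASES))
    stop("probe contains characters outside A/C/G/T")
  if (pseudo <= 0 || pseudo >= 0.5) stop("pseudo must be in (0, 0.5)")
  if (is.null(background))
    background <- stats::setNames(rep(0.25, 4), DNA_BASES)
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0))
    stop("background must give strictly positive A/C/G/T probabilities")
  background <- stats::setNames(unname(background) / sum(background),
                                DNA_BASES)
  L <- length(bases)
  bgdata <- unname(background)
  freqs <- matrix(rep(pseudo * bgdata, L), nrow = 4L,
                  dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(L))
    freqs[bases[j], j] <- freqs[bases[j], j] + (1 - pseudo)
  scores <- log2(freqs / bgdata)
  structure(list(name = name, probe = probe, length = L, freqs = freqs,
                 scores = scores, background = background),
            class = "ProbeMatrix")
}

#' @export
print.ProbeMatrix <- function(x, ...) {
  cat("ProbeMatrix", x$name, ":", x$length, "nt, max score",
      round(sum(apply(x$scores, 2, max)), 2), "bits\n")
  invisible(x)
}

#' Exact score-to-p-value mapping for a probe matrix
#'
#' Computes, by column-wise convolution of the discretised score
#' distribution, the exact probability that a background-distributed L-mer
#' scores at least s, for every achievable discretised score s. Scores are
#' binned at \code{granularity} bits; with the default 1/1000 bit the
#' discretisation error is negligible against the 1e-8 decision cutoff.
#' The mapping is non-increasing and equals 1 at the minimum possible
#' score.
#'
#' @param matrix a \code{ProbeMatrix}.
#' @param granularity score bin width in bits (> 0).
#' @param max_bins guard on table size; exceeding it is an error suggesting
#'   a coarser granularity.
#' @return an object of class \code{ProbePValueTable}: list with
#'   \code{granularity}, \code{kmin} (integer bin of the minimal score) and
#'   \code{tail} (vector, \code{tail[i]} = P(score >= kmin + i - 1 bins)).
#' @export
exact_pvalue_table <- function(matrix, granularity = 1 / 1000,
                               max_bins = 5e6) {
  stopifnot(inherits(matrix, "ProbeMatrix"), granularity > 0)
  k <- round(matrix$scores / granularity)  # 4 x L integer bins
  kmin <- sum(apply(k, 2, min))
  kmax <- sum(apply(k, 2, max))
  nbins <- kmax - kmin + 1
  if (nbins > max_bins)
    stop("p-value table would need ", nbins,
         " bins; use a coarser granularity")
  # dist[i] = P(partial score == off + i - 1), convolved column by column
  dist <- 1
  off <- 0
  bg <- matrix$background
  for (j in seq_len(matrix$length)) {
    cmin <- min(k[, j]); cmax <- max(k[, j])
    new <- numeric(length(dist) + cmax - cmin)
    for (b in 1:4) {
      sh <- k[b, j] - cmin
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + bg[b] * dist
    }
    dist <- new
    off <- off + cmin
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)  # guard tiny accumulation error
  structure(list(granularity = granularity, kmin = off, tail = tail),
            class = "ProbePValueTable")
}

#' Look up the exact p-value of a match score
#'
#' @param table a \code{ProbePValueTable}.
#' @param score score in bits (vectorised).
#' @return P(background L-mer scores >= score), in (0, 1].
#' @export
pvalue_lookup <- function(table, score) {
  kk <- round(score / table$granularity)
  i <- kk - table$kmin + 1
  out <- numeric(length(i))
  out[i <= 1] <- 1
  above <- i > length(table$tail)
  # score above the achievable maximum cannot arise from scanning; clamp
  out[above] <- table$tail[length(table$tail)]
  mid <- !above & i > 1
  out[mid] <- table$tail[i[mid]]
  out
}

# integer codes 1..4 for A/C/G/T, NA otherwise
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], DNA_BASES)
}

#' Scan a sequence with a probe matrix on both strands
#'
#' Every offset of the sequence (and of its reverse complement) is scored;
#' windows containing non-ACGT characters are skipped.
#'
#' @param matrix a \code{ProbeMatrix}.
#' @param table matching \code{ProbePValueTable}.
#' @param seq DNA string.
#' @return data.frame with \code{offset} (0-based, on the given strand's
#'   forward coordinates), \code{strand}, \code{score}, \code{pvalue};
#'   zero rows if the sequence is shorter than the probe.
#' @export
scan_sequence <- function(matrix, table, seq) {
  L <- matrix$length
  scan1 <- function(s, strand) {
    code <- encode_dna(s)
    n <- length(code) - L + 1L
    if (n < 1L)
      return(data.frame(offset = integer(), strand = character(),
                        score = numeric(), pvalue = numeric()))
    sc <- numeric(n)
    ok <- rep(TRUE, n)
    for (j in seq_len(L)) {
      cj <- code[seq_len(n) + j - 1L]
      bad <- is.na(cj)
      ok <- ok & !bad
      cj[bad] <- 1L
      sc <- sc + matrix$scores[cbind(cj, j)]
    }
    if (strand == "-") {
      # report offsets on the forward sequence
      fwd_off <- length(code) - (seq_len(n) - 1L) - L
    } else fwd_off <- seq_len(n) - 1L
    data.frame(offset = fwd_off[ok], strand = strand, score = sc[ok],
               pvalue = pvalue_lookup(table, sc[ok]))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rbind(scan1(seq, "+"), scan1(rc, "-"))
}

#' Estimate 0-order background base probabilities from a genome
#' @param assembly a \code{GenomeAssembly} with sequence.
#' @return named probability vector over A/C/G/T.
#' @export
genome_background <- function(assembly) {
  if (is.null(assembly$sequence)) stop("assembly carries no sequence")
  f <- colSums(Biostrings::alphabetFrequency(assembly$sequence)[,
                                                                DNA_BASES,
                                                                drop = FALSE])
  f / sum(f)
}

#' Read probe oligos from a FASTA file
#' @param path FASTA with one record per probe.
#' @return named character vector of probe sequences.
#' @export
read_probes_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Remove consensus sites that match a hybridization probe
#'
#' Each site's genomic sequence is scanned against every probe matrix on
#' both strands; a site with any match below \code{p_cutoff} is a direct
#' DNA:probe capture artifact and is removed. Best-match p-values are
#' per-position (no multiple-testing correction across offsets), matching
#' the convention of motif scanners that report per-match p. Sites whose
#' sequence is more than half N are skipped with a warning and retained.
#'
#' @param sites data.frame of consensus sites (\code{chrom}, \code{start},
#'   \code{end}, ...).
#' @param genome a \code{GenomeAssembly} with sequence.
#' @param probes named character vector of probe oligos (both probe sets
#'   together), or a FASTA path.
#' @param p_cutoff removal threshold on the exact match p-value.
#' @param background base probabilities; default estimated from the genome.
#' @param pseudo pseudo-frequency for \code{\link{build_probe_matrix}}.
#' @param granularity bin width for \code{\link{exact_pvalue_table}}.
#' @param flank bp of genomic context added on each side of a site before
#'   scanning (default 0: the site interval only).
#' @return list with data.frames \code{retained}, \code{removed} and
#'   \code{matches} (site row index, probe, offset, strand, score, pvalue
#'   of the best sub-cutoff match per removed site).
#' @export
scan_and_filter <- function(sites, genome, probes, p_cutoff = 1e-8,
                            background = NULL, pseudo = 0.01,
                            granularity = 1 / 1000, flank = 0L) {
  if (is.character(probes) && length(probes) == 1L && file.exists(probes))
    probes <- read_probes_fasta(probes)
  if (is.null(names(probes)))
    names(probes) <- paste0("probe_", seq_along(probes))
  if (is.null(background)) background <- genome_background(genome)
  mats <- lapply(seq_along(probes), function(i)
    build_probe_matrix(probes[[i]], background, pseudo, names(probes)[i]))
  tabs <- lapply(mats, exact_pvalue_table, granularity = granularity)
  removed <- logical(nrow(sites))
  matches <- list()
  for (i in seq_len(nrow(sites))) {
    a <- max(0L, sites$start[i] - flank)
    b <- min(genome$seqlengths[[sites$chrom[i]]], sites$end[i] + flank)
    s <- assembly_sequence(genome, sites$chrom[i], a, b)
    nfrac <- mean(strsplit(s, "")[[1L]] == "N")
    if (nfrac > 0.5) {
      warning("site ", i, " sequence is >50% N; skipped and retained")
      next
    }
    for (m in seq_along(mats)) {
      hits <- scan_sequence(mats[[m]], tabs[[m]], s)
      hits <- hits[hits$pvalue < p_cutoff, , drop = FALSE]
      if (nrow(hits)) {
        removed[i] <- TRUE
        best <- hits[which.min(hits$pvalue), ]
        matches[[length(matches) + 1L]] <- data.frame(
          site = i, probe = mats[[m]]$name, offset = best$offset,
          strand = best$strand, score = best$score, pvalue = best$pvalue)
      }
    }
  }
  list(retained = sites[!removed, , drop = FALSE],
       removed = sites[removed, , drop = FALSE],
       matches = if (length(matches)) do.call(rbind, matches)
       else data.frame(site = integer(), probe = character(),
                       offset = integer(), strand = character(),
                       score = numeric(), pvalue = numeric()))
}
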