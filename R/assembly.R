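#' Genome assembly container
#'
#' Holds per-chromosome lengths and, optionally, the chromosome sequences.
#' All pipeline coordinates are 0-based half-open (BED convention) and are
#' validated against the assembly bounds. Chromosome names are taken
#' verbatim: no "chr" prefix normalisation is attempted, and a name mismatch
#' between files on the same assembly is a hard error.
#'
#' @param seqlengths named integer vector of chromosome lengths (bp).
#' @param sequence optional \link[Biostrings]{DNAStringSet} (names matching
#'   \code{seqlengths}); each sequence must have exactly the declared length.
#' @return an object of class \code{GenomeAssembly}.
#' @examples
#' genome_assembly(c(chr1 = 1000L, chr2 = 500L))
#' @export
genome_assembly <- function(seqlengths, sequence = NULL) {
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stop("seqlengths must be a named vector with non-empty names")
  if (anyDuplicated(names(seqlengths)))
    stop("duplicated chromosome names in seqlengths")
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  if (any(is.na(seqlengths)) || any(seqlengths <= 0L))
    stop("chromosome lengths must be positive integers")
  if (!is.null(sequence)) {
    if (!methods::is(sequence, "DNAStringSet"))
      sequence <- Biostrings::DNAStringSet(unlist(sequence))
    missing <- setdiff(names(seqlengths), names(sequence))
    if (length(missing))
      stop("sequence missing for chromosome(s): ", paste(missing, collapse = ", "))
    w <- Biostrings::width(sequence)[match(names(seqlengths), names(sequence))]
    bad <- names(seqlengths)[w != seqlengths]
    if (length(bad))
      stop("sequence length disagrees with declared length for: ",
           paste(bad, collapse = ", "))
    sequence <- sequence[names(seqlengths)]
  }
  structure(list(seqlengths = seqlengths, sequence = sequence),
            class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly:", length(x$seqlengths), "chromosome(s),",
      format(sum(as.numeric(x$seqlengths)), big.mark = ","), "bp",
      if (is.null(x$sequence)) "(lengths only)" else "(with sequence)", "\n")
  invisible(x)
}

#' Read a genome assembly from a FASTA file
#'
#' @param path FASTA file with one record per chromosome.
#' @return a \code{GenomeAssembly} with sequence.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after whitespace; use first token
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  genome_assembly(stats::setNames(Biostrings::width(seqs), names(seqs)), seqs)
}

#' Write a genome assembly to FASTA
#'
#' @param assembly a \code{GenomeAssembly} carrying sequence.
#' @param path output path.
#' @export
write_genome_fasta <- function(assembly, path) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  if (is.null(assembly$sequence)) stop("assembly carries no sequence")
  Biostrings::writeXStringSet(assembly$sequence, path, width = 70L)
  invisible(path)
}

# internal: validate chrom/start/end against an assembly; 0-based half-open
check_bounds <- function(chrom, start, end, assembly, what = "interval") {
  known <- names(assembly$seqlengths)
  bad <- !(chrom %in% known)
  if (any(bad))
    stop("unknown chromosome(s) for this assembly: ",
         paste(unique(chrom[bad]), collapse = ", "))
  len <- assembly$seqlengths[chrom]
  if (any(start < 0L) || any(end > len) || any(start >= end))
    stop(what, " out of assembly bounds or empty (0-based half-open expected)")
  invisible(TRUE)
}

#' Fetch the sequence of a genomic interval
#'
#' @param assembly a \code{GenomeAssembly} with sequence.
#' @param chrom,start,end 0-based half-open coordinates.
#' @return a character DNA string (plus strand).
#' @export
assembly_sequence <- function(assembly, chrom, start, end) {
  if (is.null(assembly$sequence)) stop("assembly carries no sequence")
  check_bounds(chrom, start, end, assembly)
  as.character(Biostrings::subseq(assembly$sequence[[chrom]], start + 1L, end))
}
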