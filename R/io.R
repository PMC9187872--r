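#' Read a 4-column bedGraph into a coverage track
#'
#' Lines beginning with \code{track}, \code{browser} or \code{#} are
#' skipped. Records may arrive unsorted; overlapping records are a
#' validation error. Records beyond the assembly bounds are an error.
#'
#' @param path bedGraph file.
#' @param assembly a \code{GenomeAssembly}.
#' @return a \code{CoverageTrack}.
#' @export
read_bedgraph <- function(path, assembly) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(coverage_track(assembly, data.frame(
      chrom = character(), start = integer(), end = integer(),
      value = numeric())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", lineno[which(nf < 4L)[1L]],
         " in ", path, ": expected 4 tab-separated fields")
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  value <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop("malformed bedGraph line ", lineno[bad[1L]], " in ", path,
         ": non-numeric start/end/value")
  coverage_track(assembly, data.frame(
    chrom = m[, 1L], start = start, end = end, value = value))
}

#' Write a coverage track as bedGraph
#'
#' Only non-zero segments are written (zero is implicit), so a
#' write-then-read round trip reproduces identical per-base values.
#'
#' @param track a \code{CoverageTrack}.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  seg <- track$segments
  utils::write.table(
    data.frame(seg$chrom, seg$start, seg$end,
               format(seg$value, trim = TRUE, scientific = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from a narrowPeak (BED6+4) file
#'
#' Column 10 is the summit offset from \code{start}; \code{-1} means the
#' summit is unknown and is stored as \code{NA} (it can be recomputed later
#' from coverage with \code{\link{region_max}}). An offset at or beyond the
#' peak length is a validation error. The column-5 score is kept verbatim
#' but treated as opaque; ranking inside the pipeline uses p-values.
#'
#' @param path narrowPeak file.
#' @return data.frame of peaks with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}, \code{strand}, \code{signal},
#'   \code{pvalue}, \code{qvalue}, \code{summit} (absolute 0-based position
#'   or \code{NA}).
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "numeric", "numeric", "numeric",
                                         "integer"),
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "signal",
                                        "pvalue", "qvalue", "offset"))
  if (any(df$offset >= df$end - df$start))
    stop("narrowPeak summit offset >= peak length (row ",
         which(df$offset >= df$end - df$start)[1L], ")")
  if (any(df$offset < -1L))
    stop("narrowPeak summit offset below -1")
  df$summit <- ifelse(df$offset >= 0L, df$start + df$offset, NA_integer_)
  df$offset <- NULL
  df
}

#' Write peaks as narrowPeak
#' @param peaks data.frame as returned by \code{\link{read_narrowpeak}} or
#'   \code{\link{call_peaks}}.
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  offset <- ifelse(is.na(peaks$summit), -1L,
                   as.integer(peaks$summit - peaks$start))
  df <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    if (is.null(peaks$name)) "." else peaks$name,
    if (is.null(peaks$score)) 0 else peaks$score,
    if (is.null(peaks$strand)) "." else peaks$strand,
    if (is.null(peaks$signal)) 0 else peaks$signal,
    if (is.null(peaks$pvalue)) -1 else peaks$pvalue,
    if (is.null(peaks$qvalue)) -1 else peaks$qvalue,
    offset)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# parse one GTF attribute ("gene_id" etc.) out of column 9
gtf_attribute <- function(attr, key) {
  pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
  m <- regmatches(attr, regexec(pat, attr))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
}

#' Read gene models from a GTF file
#'
#' GTF coordinates are 1-based inclusive and converted to the internal
#' 0-based half-open convention at this boundary. One model is built per
#' \code{gene_id}: the gene interval is the span of all its features, the
#' exon set is the union of its exon records (overlaps between transcripts
#' are merged), and the transcription start site (TSS) is the first
#' transcribed base: \code{start} on the + strand, \code{end - 1} on the
#' - strand. The transcription end site (TES) is the opposite extremity.
#'
#' @param path GTF file with \code{gene} and/or \code{exon} features.
#' @return an object of class \code{GeneModels}: a list with data.frames
#'   \code{genes} (gene_id, gene_name, chrom, start, end, strand, tss, tes)
#'   and \code{exons} (gene_id, chrom, start, end).
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9L))
    stop("malformed GTF line ", which(lengths(parts) < 9L)[1L])
  feat <- vapply(parts, `[`, "", 3L)
  use <- feat %in% c("gene", "exon", "transcript")
  parts <- parts[use]; feat <- feat[use]
  if (!length(parts)) stop("no gene/exon features in ", path)
  chrom <- vapply(parts, `[`, "", 1L)
  start1 <- as.integer(vapply(parts, `[`, "", 4L))
  end1 <- as.integer(vapply(parts, `[`, "", 5L))
  strand <- vapply(parts, `[`, "", 7L)
  attr9 <- vapply(parts, `[`, "", 9L)
  gene_id <- gtf_attribute(attr9, "gene_id")
  if (anyNA(gene_id))
    stop("GTF record without gene_id attribute (feature line ",
         which(is.na(gene_id))[1L], ")")
  gene_name <- gtf_attribute(attr9, "gene_name")
  # convert to 0-based half-open
  start0 <- start1 - 1L
  end0 <- end1
  ids <- unique(gene_id)
  rows <- lapply(ids, function(id) {
    sel <- gene_id == id
    ch <- unique(chrom[sel]); st <- unique(strand[sel])
    if (length(ch) != 1L)
      stop("gene ", id, " spans multiple chromosomes")
    st <- st[st %in% c("+", "-")]
    st <- if (length(st)) st[1L] else "."
    s <- min(start0[sel]); e <- max(end0[sel])
    nm <- gene_name[sel][!is.na(gene_name[sel])]
    data.frame(gene_id = id,
               gene_name = if (length(nm)) nm[1L] else id,
               chrom = ch, start = s, end = e, strand = st,
               tss = if (st == "-") e - 1L else s,
               tes = if (st == "-") s else e - 1L)
  })
  genes <- do.call(rbind, rows)
  esel <- feat == "exon"
  if (any(esel)) {
    er <- IRanges::IRanges(start0[esel] + 1L, end0[esel])  # 1-based for IRanges
    grp <- gene_id[esel]
    merged <- lapply(split(seq_along(er), grp), function(i) {
      r <- IRanges::reduce(er[i])
      data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    })
    exons <- do.call(rbind, Map(function(id, d) {
      data.frame(gene_id = id,
                 chrom = genes$chrom[match(id, genes$gene_id)],
                 start = d$start, end = d$end)
    }, names(merged), merged))
  } else {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer())
  }
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", nrow(x$genes), "gene(s),", nrow(x$exons),
      "merged exon(s)\n")
  invisible(x)
}

#' Read repeat elements from a BED6 file
#'
#' The name column carries the repeat class; anything outside
#' \{SINE, LINE, LTR, simple_repeat\} is mapped to \code{other}.
#'
#' @param path BED6 file.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{class}.
#' @export
read_bed_repeats <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("repeat BED needs at least 4 columns")
  cls <- df[[4L]]
  cls[!cls %in% c("SINE", "LINE", "LTR", "simple_repeat")] <- "other"
  data.frame(chrom = as.character(df[[1L]]), start = as.integer(df[[2L]]),
             end = as.integer(df[[3L]]), class = cls)
}

#' Write consensus sites as BED6
#'
#' The name field packs the support metadata
#' (\code{site_<i>|support=<n>}); the score column carries the summit
#' position relative to start for quick inspection.
#' @param sites data.frame of consensus sites.
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  name <- sprintf("site_%d|support=%d", seq_len(nrow(sites)),
                  if (is.null(sites$support)) rep(3L, nrow(sites))
                  else sites$support)
  df <- data.frame(sites$chrom, sites$start, sites$end, name,
                   sites$summit - sites$start, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a numeric TSV matrix with row identifiers in the first column
#' @param path TSV file with a header line.
#' @return numeric matrix with rownames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a numeric matrix as TSV with an id column
#' @param m matrix with rownames.
#' @param path output file.
#' @param id_name header of the identifier column.
#' @export
write_tsv_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
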