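SITE_CATEGORIES <- c("promoter", "TTS", "exon", "SINE", "LINE", "LTR",
                     "simple_repeat", "intron", "intergenic")

# strand-aware window around an anchor: w = c(upstream, downstream) relative
# to transcription direction; returns c(lo, hi) in genome coordinates
anchored_window <- function(anchor, strand, w) {
  if (strand == "-") c(anchor - w[2L], anchor - w[1L])
  else c(anchor + w[1L], anchor + w[2L])
}

#' Classify one genomic site by its summit position
#'
#' Fixed priority: promoter > TTS > exon > repeat class > intron >
#' intergenic. The promoter window is strand-aware around the TSS
#' (default 1000 bp upstream to 100 bp downstream); the transcription
#' termination (TTS) window mirrors it around the TES (100 bp upstream to
#' 1000 bp downstream of the end of transcription). Classification is by
#' the summit point, not interval overlap, which gives every site exactly
#' one category; set \code{point = FALSE} to let any overlap of the site
#' interval count instead.
#'
#' @param site one-row data.frame with \code{chrom}, \code{start},
#'   \code{end}, \code{summit}.
#' @param genes a \code{GeneModels} object.
#' @param repeats repeat data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{class}) or NULL.
#' @param promoter_window c(upstream, downstream) in bp relative to the
#'   TSS, upstream negative.
#' @param point classify by summit point (default) or by interval overlap.
#' @return one of \code{promoter, TTS, exon, SINE, LINE, LTR,
#'   simple_repeat, intron, intergenic}.
#' @export
classify_site <- function(site, genes, repeats = NULL,
                          promoter_window = c(-1000L, 100L), point = TRUE) {
  g <- genes$genes[genes$genes$chrom == site$chrom, , drop = FALSE]
  if (point) { qlo <- site$summit; qhi <- site$summit + 1L }
  else { qlo <- site$start; qhi <- site$end }
  hits_window <- function(lohi) qhi > lohi[1L] && qlo <= lohi[2L]
  if (nrow(g)) {
    for (i in seq_len(nrow(g)))
      if (hits_window(anchored_window(g$tss[i], g$strand[i], promoter_window)))
        return("promoter")
    for (i in seq_len(nrow(g)))
      if (hits_window(anchored_window(g$tes[i], g$strand[i],
                                      c(-promoter_window[2L],
                                        -promoter_window[1L]))))
        return("TTS")
    ex <- genes$exons[genes$exons$chrom == site$chrom, , drop = FALSE]
    if (nrow(ex) && any(qhi > ex$start & qlo < ex$end)) return("exon")
  }
  if (!is.null(repeats)) {
    rp <- repeats[repeats$chrom == site$chrom, , drop = FALSE]
    hit <- which(qhi > rp$start & qlo < rp$end)
    if (length(hit)) {
      cls <- rp$class[hit[1L]]
      if (cls %in% SITE_CATEGORIES) return(cls)
    }
  }
  if (nrow(g) && any(qhi > g$start & qlo < g$end)) return("intron")
  "intergenic"
}

#' Nearest gene of a site by TSS distance
#'
#' The gene minimising \code{|summit - TSS|} on the site's chromosome; ties
#' are broken by lexicographic gene id. The signed distance respects gene
#' orientation: negative means the summit lies upstream of the TSS.
#'
#' @param site one-row data.frame with \code{chrom} and \code{summit}.
#' @param genes a \code{GeneModels} object.
#' @return list with \code{gene_id} (NA when the chromosome has no gene)
#'   and \code{distance} (bp; \code{Inf} when unbounded).
#' @export
nearest_gene <- function(site, genes) {
  g <- genes$genes[genes$genes$chrom == site$chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = Inf))
  d <- abs(site$summit - g$tss)
  o <- order(d, g$gene_id)
  i <- o[1L]
  signed <- if (g$strand[i] == "-") g$tss[i] - site$summit
  else site$summit - g$tss[i]
  list(gene_id = g$gene_id[i], distance = signed)
}

#' Annotate a set of consensus sites
#'
#' Applies \code{\link{classify_site}} and \code{\link{nearest_gene}} to
#' every site.
#'
#' @inheritParams classify_site
#' @param sites data.frame of sites.
#' @return the sites data.frame with added \code{category},
#'   \code{nearest_gene} and \code{tss_distance} columns.
#' @export
annotate_sites <- function(sites, genes, repeats = NULL,
                           promoter_window = c(-1000L, 100L), point = TRUE) {
  if (is.null(repeats))
    warning("no repeat annotation supplied: repeat categories will be empty")
  n <- nrow(sites)
  cat <- character(n); ng <- character(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    s <- sites[i, ]
    cat[i] <- classify_site(s, genes, repeats, promoter_window, point)
    nn <- nearest_gene(s, genes)
    ng[i] <- nn$gene_id; dist[i] <- nn$distance
  }
  sites$category <- cat
  sites$nearest_gene <- ng
  sites$tss_distance <- dist
  sites
}

#' Tabulate annotation categories
#'
#' @param annotations data.frame with a \code{category} column (as from
#'   \code{\link{annotate_sites}}); must be non-empty.
#' @return data.frame with \code{category}, \code{count}, \code{fraction}
#'   over the full category vocabulary (fractions sum to 1).
#' @export
annotation_summary <- function(annotations) {
  if (!nrow(annotations)) stop("empty annotation set")
  counts <- table(factor(annotations$category, levels = SITE_CATEGORIES))
  data.frame(category = SITE_CATEGORIES,
             count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotations))
}
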