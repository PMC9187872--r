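#' Configuration for the synthetic-data generators
#'
#' One object collects every knob of the simulators, with defaults chosen
#' to emulate the experimental design the pipeline targets: a dual
#' probe-set ChIRP experiment in biological triplicate over a small
#' genome, a knockdown-versus-control expression time course (2 conditions
#' x 2 days x 4 replicates) coupled to one designated lncRNA, and a 5 vs 5
#' label-free pull-down with intensity-dependent missingness. All
#' randomness is funnelled through \code{seed}; every generator is a pure
#' function of its config.
#'
#' @param seed integer master seed.
#' @param n_chrom,chrom_length genome shape (bp; length >= 10 kb).
#' @param n_genes,gene_length_range gene models per genome and their
#'   length range.
#' @param repeats_per_class repeat elements placed per class.
#' @param n_sites planted genuine binding sites.
#' @param site_width planted site width (bp).
#' @param fold coverage fold-enrichment of planted sites over background
#'   (> 1; default 15).
#' @param n_contaminants probe-capture artifact loci (elevated in one
#'   probe set only, carrying a verbatim probe subsequence).
#' @param background_rate background tag density (tags per bp).
#' @param replicate_noise_sd lognormal SD of the per-replicate,
#'   per-site enrichment noise.
#' @param probe_length,probes_per_set tiling probes per probe set.
#' @param n_expr_genes genes in the expression simulation.
#' @param frac_up,frac_down planted regulated fractions.
#' @param effect_log2fc planted |log2 fold change| of regulated genes.
#' @param n_targets lncRNA-coupled target genes.
#' @param coupling strength of the lncRNA-target coupling.
#' @param expr_noise_sd biological noise SD (log scale).
#' @param n_proteins,n_enriched LFQ matrix shape and planted enriched
#'   proteins.
#' @param lfq_effect planted log2 enrichment toward full-length.
#' @param lfq_sd within-group SD of log2 intensities.
#' @param flag_rate rate of reverse/contaminant flags.
#' @param missing_mid,missing_scale logistic missingness midpoint and
#'   scale on the log2 intensity axis.
#' @return a \code{SimulationConfig} list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 2L, chrom_length = 100000L,
                              n_genes = 30L,
                              gene_length_range = c(2000L, 6000L),
                              repeats_per_class = 6L,
                              n_sites = 20L, site_width = 300L, fold = 15,
                              n_contaminants = 4L,
                              background_rate = 0.1,
                              replicate_noise_sd = 0.15,
                              probe_length = 20L, probes_per_set = 10L,
                              n_expr_genes = 2000L,
                              frac_up = 0.1, frac_down = 0.1,
                              effect_log2fc = 2,
                              n_targets = 40L, coupling = 1,
                              expr_noise_sd = 0.2,
                              n_proteins = 500L, n_enriched = 30L,
                              lfq_effect = 2, lfq_sd = 0.5,
                              flag_rate = 0.02,
                              missing_mid = 21.5, missing_scale = 0.6) {
  stopifnot(chrom_length >= 10000L, fold > 1)
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

# deterministic sub-seed per generator, kept below 2^31
sub_seed <- function(cfg, k) (as.integer(cfg$seed) * 7919L + k) %% 2147483647L

#' Simulate a genome: sequence, gene models and repeat elements
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T. Non-overlapping
#' gene models with 2-5 exons are placed left to right with random gaps;
#' repeat elements of each class land in the remaining intergenic space.
#'
#' @param config a \code{SimulationConfig}.
#' @return list with \code{assembly} (\code{GenomeAssembly} with
#'   sequence), \code{genes} (\code{GeneModels}), \code{repeats}
#'   (data.frame).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(sub_seed(config, 1L), {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      paste(sample(DNA_BASES, config$chrom_length, replace = TRUE),
            collapse = ""), ""))
    names(seqs) <- chroms
    assembly <- genome_assembly(
      stats::setNames(rep(config$chrom_length, config$n_chrom), chroms),
      seqs)
    per_chrom <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chrom + 1L)))
    genes <- list(); exons <- list(); gi <- 0L
    for (ci in seq_along(chroms)) {
      pos <- 2000L
      for (k in seq_len(per_chrom[ci])) {
        glen <- sample(seq(config$gene_length_range[1L],
                           config$gene_length_range[2L]), 1L)
        gap <- sample(1500:4000, 1L)
        start <- pos + gap
        end <- start + glen
        if (end > config$chrom_length - 2000L) break
        gi <- gi + 1L
        strand <- sample(c("+", "-"), 1L)
        id <- sprintf("gene%03d", gi)
        genes[[gi]] <- data.frame(
          gene_id = id, gene_name = id, chrom = chroms[ci],
          start = start, end = end, strand = strand,
          tss = if (strand == "-") end - 1L else start,
          tes = if (strand == "-") start else end - 1L)
        n_ex <- sample(2:5, 1L)
        bounds <- sort(sample(seq(start + 100L, end - 100L, by = 50L),
                              2L * n_ex - 2L))
        es <- c(start, bounds[seq(2L, length(bounds), by = 2L)])
        ee <- c(bounds[seq(1L, length(bounds), by = 2L)], end)
        exons[[gi]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                  start = es, end = ee)
        pos <- end
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    classes <- c("SINE", "LINE", "LTR", "simple_repeat")
    reps <- list()
    for (cl in classes) {
      for (k in seq_len(config$repeats_per_class)) {
        repeat {
          ch <- sample(chroms, 1L)
          w <- sample(150:500, 1L)
          s <- sample.int(config$chrom_length - w, 1L)
          g <- genes[genes$chrom == ch, , drop = FALSE]
          if (!any(s < g$end & s + w > g$start)) break  # intergenic only
        }
        reps[[length(reps) + 1L]] <- data.frame(
          chrom = ch, start = s, end = s + w, class = cl)
      }
    }
    repeats <- do.call(rbind, reps)
    list(assembly = assembly,
         genes = structure(list(genes = genes, exons = exons),
                           class = "GeneModels"),
         repeats = repeats[order(repeats$chrom, repeats$start), ])
  })
}

#' Simulate dual-probe ChIRP coverage in triplicate
#'
#' Tag density is Poisson background (piecewise over 10-bp bins). Planted
#' genuine sites receive fold-elevated coverage in \emph{both} probe-set
#' tracks with independent lognormal replicate noise; contaminant loci are
#' elevated in one probe set only and a verbatim copy of one of that set's
#' probes is written into the genome sequence at the locus centre, so they
#' emulate direct DNA:probe capture. Probes tile a synthetic transcript,
#' alternating between the even and odd set.
#'
#' @param config a \code{SimulationConfig}.
#' @param genome result of \code{\link{simulate_genome}}.
#' @return list with \code{tracks} (list \code{[[replicate]][[probe_set]]}
#'   of \code{CoverageTrack}s), \code{probes} (list with \code{even} and
#'   \code{odd} named vectors), \code{assembly} (sequence with contaminant
#'   probe copies planted) and \code{truth} (data.frame of planted loci
#'   with \code{type} real/contaminant).
#' @export
simulate_chirp <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(sub_seed(config, 2L), {
    assembly <- genome$assembly
    chroms <- names(assembly$seqlengths)
    L <- config$chrom_length
    # synthetic transcript tiled by alternating probes
    transcript <- paste(sample(DNA_BASES,
                               2L * config$probes_per_set *
                                 config$probe_length, replace = TRUE),
                        collapse = "")
    starts <- seq(1L, by = config$probe_length,
                  length.out = 2L * config$probes_per_set)
    all_probes <- substring(transcript, starts,
                            starts + config$probe_length - 1L)
    even <- stats::setNames(all_probes[seq(2L, length(all_probes), 2L)],
                            sprintf("even_%02d",
                                    seq_len(config$probes_per_set)))
    odd <- stats::setNames(all_probes[seq(1L, length(all_probes), 2L)],
                           sprintf("odd_%02d",
                                   seq_len(config$probes_per_set)))
    # place planted loci >= 5 kb apart on a per-chromosome grid
    n_loci <- config$n_sites + config$n_contaminants
    slots <- list()
    for (ch in chroms) {
      anchors <- seq(5000L, L - 5000L - config$site_width, by = 5000L)
      slots[[ch]] <- data.frame(chrom = ch, anchor = anchors)
    }
    slots <- do.call(rbind, slots)
    if (n_loci > nrow(slots))
      stop("requested planted loci exceed genome capacity")
    pick <- slots[sort(sample.int(nrow(slots), n_loci)), ]
    jitter <- sample(0:2000, n_loci, replace = TRUE)
    truth <- data.frame(
      chrom = pick$chrom,
      start = pick$anchor + jitter,
      type = rep(c("real", "contaminant"),
                 c(config$n_sites, config$n_contaminants))[
                   sample.int(n_loci)])
    truth$end <- truth$start + config$site_width
    truth$probe_set <- rep(NA_character_, nrow(truth))
    contam <- which(truth$type == "contaminant")
    truth$probe_set[contam] <- rep(c("even", "odd"),
                                   length.out = length(contam))
    # plant verbatim probe copies at contaminant locus centres
    seqs <- as.character(assembly$sequence)
    for (i in contam) {
      set <- truth$probe_set[i]
      pr <- if (set == "even") even[[1L + (i %% config$probes_per_set)]]
      else odd[[1L + (i %% config$probes_per_set)]]
      at <- truth$start[i] + config$site_width %/% 2L  # 0-based
      s <- seqs[[truth$chrom[i]]]
      substr(s, at + 1L, at + nchar(pr)) <- pr
      seqs[[truth$chrom[i]]] <- s
    }
    assembly <- genome_assembly(assembly$seqlengths,
                                Biostrings::DNAStringSet(seqs))
    bin <- 10L
    tracks <- list()
    for (r in 1:3) {
      tracks[[r]] <- list()
      for (set in c("even", "odd")) {
        segs <- list()
        for (ch in chroms) {
          nb <- L %/% bin
          rate <- rep(config$background_rate, nb)
          for (i in seq_len(nrow(truth))) {
            if (truth$chrom[i] != ch) next
            boost <- config$fold *
              stats::rlnorm(1L, 0, config$replicate_noise_sd)
            bins <- (truth$start[i] %/% bin):((truth$end[i] - 1L) %/% bin)
            if (truth$type[i] == "real" || truth$probe_set[i] == set) {
              # bell-shaped tag-density profile peaking at the locus
              # centre, the shape pulled-down fragments produce around a
              # point of RNA contact; the summit-concordance rule assumes
              # summits estimate that point
              centre <- (truth$start[i] + truth$end[i]) / 2
              x <- (bins + 0.5) * bin
              prof <- exp(-(x - centre)^2 / (2 * (config$site_width / 4)^2))
              rate[bins + 1L] <- config$background_rate *
                (1 + (boost - 1) * prof)
            }
          }
          counts <- stats::rpois(nb, rate * bin)
          nz <- which(counts > 0L)
          if (length(nz))
            segs[[length(segs) + 1L]] <- data.frame(
              chrom = ch, start = (nz - 1L) * bin, end = nz * bin,
              value = counts[nz] / bin)
        }
        seg <- if (length(segs)) do.call(rbind, segs) else
          data.frame(chrom = character(), start = integer(),
                     end = integer(), value = numeric())
        tracks[[r]][[set]] <- coverage_track(assembly, seg)
      }
    }
    list(tracks = tracks, probes = list(even = even, odd = odd),
         assembly = assembly,
         truth = truth[order(truth$chrom, truth$start), ])
  })
}

#' Simulate a knockdown expression time course with DE statistics
#'
#' Negative-binomial counts for 2 conditions x 2 days x 4 replicates are
#' converted to TPM. Planted fractions of genes carry log2 fold effects in
#' the knockdown; a designated lncRNA gene is reduced to ~50% in the
#' knockdown, and coupled target genes co-vary with the lncRNA's
#' per-sample deviations with a chosen sign per day. DE statistics are
#' emitted from generator truth -- for null genes the stat is standard
#' normal, for planted genes it is the effect over its simulated standard
#' error -- and the FDR column is a Benjamini-Hochberg adjustment of the
#' implied normal p-values, so the DESeq2-shaped columns exist without a
#' DE package.
#'
#' @param config a \code{SimulationConfig}.
#' @return list with \code{expr} (genes x samples TPM), \code{meta}
#'   (sample metadata), \code{de} (gene/day/stat/fdr), \code{lnc_gene},
#'   and \code{truth} (planted regulation and coupling per gene).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(sub_seed(config, 3L), {
    n <- config$n_expr_genes
    genes <- sprintf("g%04d", seq_len(n))
    lnc <- "lncRNA"
    meta <- expand.grid(replicate = 1:4, condition = c("CON", "KD"),
                        day = c(5L, 7L), stringsAsFactors = FALSE)
    meta$sample <- with(meta, paste0(condition, "_d", day, "_r", replicate))
    n_up <- round(config$frac_up * n)
    n_down <- round(config$frac_down * n)
    reg <- rep("null", n)
    reg[seq_len(n_up)] <- "up"
    reg[n_up + seq_len(n_down)] <- "down"
    reg <- sample(reg)
    # coupled targets drawn from null genes; sign of coupling per day
    tgt_idx <- sample(which(reg == "null"), config$n_targets)
    coup_sign5 <- sample(c(-1, 1), config$n_targets, replace = TRUE)
    coup_sign7 <- sample(c(-1, 1), config$n_targets, replace = TRUE)
    base <- stats::rlnorm(n, meanlog = 4, sdlog = 1.5)
    lnc_base <- 200
    expr <- matrix(0, n + 1L, nrow(meta),
                   dimnames = list(c(genes, lnc), meta$sample))
    lnc_dev <- numeric(nrow(meta))
    for (s in seq_len(nrow(meta))) {
      kd <- meta$condition[s] == "KD"
      dev <- stats::rnorm(1L, 0, config$expr_noise_sd)
      lnc_dev[s] <- dev
      mu_lnc <- lnc_base * (if (kd) 0.5 else 1) * exp(dev)
      lfc <- numeric(n)
      if (kd) {
        lfc[reg == "up"] <- config$effect_log2fc
        lfc[reg == "down"] <- -config$effect_log2fc
      }
      # targets respond to the lncRNA's abundance itself (knockdown effect
      # included), which is what makes them correlate with it
      sign_day <- if (meta$day[s] == 5L) coup_sign5 else coup_sign7
      lfc[tgt_idx] <- lfc[tgt_idx] +
        config$coupling * sign_day * log2(mu_lnc / lnc_base)
      mu <- base * 2^lfc *
        exp(stats::rnorm(n, 0, config$expr_noise_sd / 2))
      counts <- stats::rnbinom(n + 1L, mu = c(mu, mu_lnc), size = 50)
      expr[, s] <- counts / sum(counts) * 1e6
    }
    # DE statistics from generator truth
    de <- list()
    for (d in c(5L, 7L)) {
      se <- config$effect_log2fc / 8  # simulated SE of the effect scale
      stat <- stats::rnorm(n)
      stat[reg == "up"] <- config$effect_log2fc / se + stats::rnorm(n_up)
      stat[reg == "down"] <- -config$effect_log2fc / se +
        stats::rnorm(n_down)
      p <- 2 * stats::pnorm(-abs(stat))
      de[[length(de) + 1L]] <- data.frame(
        gene_id = genes, day = d, stat = stat,
        fdr = stats::p.adjust(p, method = "BH"))
    }
    truth <- data.frame(gene_id = genes, regulation = reg,
                        coupling5 = 0, coupling7 = 0)
    truth$coupling5[tgt_idx] <- coup_sign5
    truth$coupling7[tgt_idx] <- coup_sign7
    list(expr = expr, meta = meta, de = do.call(rbind, de),
         lnc_gene = lnc, truth = truth,
         target_genes = genes[tgt_idx])
  })
}

#' Simulate a 5 vs 5 label-free pull-down intensity matrix
#'
#' Log-normal intensities with planted proteins enriched toward the
#' full-length ("fl") condition; missingness follows a logistic curve in
#' the log2 intensity (low-abundance values drop out more often), which
#' naturally produces exclusive-detection cases; reverse/contaminant flags
#' are sprinkled at the configured rate.
#'
#' @param config a \code{SimulationConfig}.
#' @param null_only if TRUE no proteins are enriched (global-null
#'   calibration runs).
#' @return list with \code{intensity} (raw scale, NA = missing),
#'   \code{condition}, \code{flags} and \code{truth}.
#' @export
simulate_lfq <- function(config, null_only = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(sub_seed(config, 4L), {
    n <- config$n_proteins
    prot <- sprintf("P%04d", seq_len(n))
    condition <- rep(c("fl", "mut"), each = 5L)
    samples <- paste0(condition, "_", rep(1:5, 2L))
    mu <- stats::rnorm(n, 25, 1.5)
    flags <- data.frame(
      reverse = stats::runif(n) < config$flag_rate,
      contaminant = stats::runif(n) < config$flag_rate,
      site = stats::runif(n) < config$flag_rate,
      row.names = prot)
    flagged <- rowSums(flags) > 0
    enriched <- logical(n)
    # decoy/contaminant rows are not genuine interactors: plant enrichment
    # on clean rows only
    if (!null_only)
      enriched[sample(which(!flagged), config$n_enriched)] <- TRUE
    lmat <- matrix(stats::rnorm(n * 10L, mu, config$lfq_sd), n, 10L,
                   dimnames = list(prot, samples))
    lmat[enriched, condition == "mut"] <-
      lmat[enriched, condition == "mut"] - config$lfq_effect
    pmiss <- stats::plogis((config$missing_mid - lmat) /
                             config$missing_scale)
    miss <- matrix(stats::runif(n * 10L) < pmiss, n, 10L)
    intensity <- 2^lmat
    intensity[miss] <- NA
    list(intensity = intensity, condition = condition, flags = flags,
         truth = data.frame(protein = prot, enriched = enriched))
  })
}

#' Write a genome simulation to standard files
#'
#' Emits FASTA, GTF (gene + exon features, 1-based inclusive) and a BED6
#' repeat file into a directory.
#'
#' @param genome result of \code{\link{simulate_genome}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  write_genome_fasta(genome$assembly, fa)
  gtf <- file.path(dir, "genes.gtf")
  g <- genome$genes$genes; e <- genome$genes$exons
  lines <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_name),
    sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            e$chrom, e$start + 1L, e$end,
            g$strand[match(e$gene_id, g$gene_id)], e$gene_id))
  writeLines(lines, gtf)
  bed <- file.path(dir, "repeats.bed")
  utils::write.table(
    data.frame(genome$repeats$chrom, genome$repeats$start,
               genome$repeats$end, genome$repeats$class, 0, "."),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fa, gtf = gtf, repeats = bed))
}
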