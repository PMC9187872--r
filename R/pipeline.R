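#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the published
#' analysis values: 200-bp maximum even/odd summit separation, probe-match
#' removal below p = 1e-8, DE gates FDR < 0.05 and |stat| > 2, proteomics
#' gates fold change > 2 and p < 0.002, s0 = 0.1, imputation down-shift 2
#' and width 0.2, permutation FDR at 0.05.
#'
#' @param seed master seed (also passed to the simulators).
#' @param summit_distance maximum even/odd summit separation (bp).
#' @param summit_distance_sense \code{"max"} (default) or \code{"min"}.
#' @param probe_p_cutoff probe decontamination p cutoff.
#' @param fdr_cut,stat_cut DE status gates.
#' @param fc_threshold,p_threshold proteomics enrichment gates.
#' @param s0,alpha,impute_d,impute_w proteomics test parameters.
#' @param peak_window,peak_p,peak_min_length simplified caller parameters.
#' @param peak_source \code{"per_probe_set"} (call on raw even/odd tracks,
#'   then pair) or \code{"take_lower"} (call on the merged track; each peak
#'   is its own pair).
#' @param sim a \code{SimulationConfig} for synthetic runs (default one
#'   with the same seed).
#' @param out_dir optional output directory for files and the run
#'   manifest.
#' @return a \code{PipelineConfig} list.
#' @export
pipeline_config <- function(seed = 1L,
                            summit_distance = 200L,
                            summit_distance_sense = "max",
                            probe_p_cutoff = 1e-8,
                            fdr_cut = 0.05, stat_cut = 2,
                            fc_threshold = 2, p_threshold = 0.002,
                            s0 = 0.1, alpha = 0.05,
                            impute_d = 2, impute_w = 0.2,
                            peak_window = 200L, peak_p = 1e-5,
                            peak_min_length = 100L,
                            peak_source = c("per_probe_set", "take_lower"),
                            sim = simulation_config(seed = seed),
                            out_dir = NULL) {
  peak_source <- match.arg(peak_source)
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' ChIRP consensus stage: tracks to decontaminated consensus sites
#'
#' Per replicate the even and odd tracks are merged (take-lower) and peaks
#' are called either per probe set (then paired by overlap and summit
#' distance) or once on the merged track. The three replicate pair lists
#' are intersected by the three-of-three rule and the surviving sites are
#' scanned against the probe oligos.
#'
#' @param tracks list \code{[[replicate]][[probe_set]]} of
#'   \code{CoverageTrack}s (3 replicates, sets "even"/"odd").
#' @param genome a \code{GenomeAssembly} with sequence (for
#'   decontamination).
#' @param probes named character vector (or list of even/odd vectors) of
#'   probe oligos.
#' @param config a \code{PipelineConfig}.
#' @return list with \code{merged} tracks, per-replicate \code{peaks} and
#'   \code{pairs}, \code{consensus}, and the decontamination result
#'   (\code{retained}, \code{removed}, \code{matches}).
#' @export
run_chirp_consensus <- function(tracks, genome, probes,
                                config = pipeline_config()) {
  stopifnot(length(tracks) == 3L)
  if (is.list(probes) && !is.null(probes$even))
    probes <- c(probes$even, probes$odd)
  merged <- lapply(tracks, function(tr)
    take_lower_merge(tr$even, tr$odd))
  pairs <- vector("list", 3L)
  peaks <- vector("list", 3L)
  for (r in 1:3) {
    if (config$peak_source == "per_probe_set") {
      pe <- call_peaks(tracks[[r]]$even, config$peak_window,
                       config$peak_p, config$peak_min_length)
      po <- call_peaks(tracks[[r]]$odd, config$peak_window,
                       config$peak_p, config$peak_min_length)
      peaks[[r]] <- list(even = pe, odd = po)
      pairs[[r]] <- pair_even_odd(pe, po, config$summit_distance,
                                  config$summit_distance_sense)
    } else {
      pm <- call_peaks(merged[[r]], config$peak_window, config$peak_p,
                       config$peak_min_length)
      peaks[[r]] <- list(merged = pm)
      pairs[[r]] <- data.frame(chrom = pm$chrom, start = pm$start,
                               end = pm$end, summit_even = pm$summit,
                               summit_odd = pm$summit,
                               summit_distance = 0L,
                               idx_even = seq_len(nrow(pm)),
                               idx_odd = seq_len(nrow(pm)))
    }
  }
  consensus <- replicate_consensus(pairs[[1L]], pairs[[2L]], pairs[[3L]])
  decon <- scan_and_filter(consensus, genome, probes,
                           p_cutoff = config$probe_p_cutoff)
  c(list(merged = merged, peaks = peaks, pairs = pairs,
         consensus = consensus), decon)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates every input from \code{config$sim}, runs the ChIRP consensus
#' chain, annotates the retained sites, integrates the expression
#' simulation (DE status, two-cluster structure, lncRNA correlations) and
#' the LFQ simulation (preprocess, impute, permutation FDR,
#' classification). When \code{config$out_dir} is set, the stage outputs
#' and a JSON run manifest recording every parameter are written there.
#'
#' @param config a \code{PipelineConfig}.
#' @return list of stage results (see details in the individual stage
#'   functions).
#' @export
run_all <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genome <- stage("simulate-genome", simulate_genome(config$sim))
  chirp <- stage("simulate-chirp", simulate_chirp(config$sim, genome))
  exprsim <- stage("simulate-expression", simulate_expression(config$sim))
  lfqsim <- stage("simulate-lfq", simulate_lfq(config$sim))

  chain <- stage("chirp-consensus",
                 run_chirp_consensus(chirp$tracks, chirp$assembly,
                                     chirp$probes, config))
  annotated <- stage("annotate",
                     annotate_sites(chain$retained, genome$genes,
                                    genome$repeats))
  summary <- if (nrow(annotated)) annotation_summary(annotated) else NULL

  targets <- c(exprsim$target_genes, exprsim$lnc_gene)
  report <- stage("integrate",
                  target_gene_report(exprsim$expr[targets, , drop = FALSE],
                                     exprsim$meta, exprsim$de,
                                     exprsim$lnc_gene,
                                     config$fdr_cut, config$stat_cut))
  de_calls <- stage("de-status", within(exprsim$de, {
    status <- de_status(stat, fdr, config$fdr_cut, config$stat_cut)
  }))

  prep <- stage("lfq-preprocess",
                lfq_preprocess(lfqsim$intensity, lfqsim$condition,
                               lfqsim$flags))
  imputed <- stage("lfq-impute",
                   lfq_impute(prep$log2, config$impute_d, config$impute_w,
                              seed = sub_seed(config$sim, 5L)))
  enr <- stage("lfq-enrich",
               permutation_fdr(imputed, prep$condition,
                               numerator = "mut", denominator = "fl",
                               s0 = config$s0, alpha = config$alpha))
  enr$enriched <- classify_enrichment(enr$log2_ratio, enr$neg_log10_p,
                                      fc_threshold = config$fc_threshold,
                                      p_threshold = config$p_threshold)
  enr$exclusive <- prep$exclusive[match(enr$protein, names(prep$exclusive))]

  res <- list(genome = genome, chirp = chirp, expression = exprsim,
              lfq = lfqsim, chain = chain, sites = annotated,
              annotation_summary = summary, target_report = report,
              de_calls = de_calls, enrichment = enr)
  if (!is.null(config$out_dir)) write_run_outputs(res, config)
  res
}

# write stage outputs plus a machine-readable manifest
write_run_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  write_genome_files(res$genome, od)
  for (r in 1:3) {
    write_bedgraph(res$chirp$tracks[[r]]$even,
                   file.path(od, sprintf("rep%d_even.bedgraph", r)))
    write_bedgraph(res$chirp$tracks[[r]]$odd,
                   file.path(od, sprintf("rep%d_odd.bedgraph", r)))
    write_bedgraph(res$chain$merged[[r]],
                   file.path(od, sprintf("rep%d_merged.bedgraph", r)))
  }
  if (nrow(res$chain$consensus))
    write_sites_bed(res$chain$consensus, file.path(od, "consensus.bed"))
  if (nrow(res$sites))
    utils::write.table(res$sites, file.path(od, "sites_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$target_report, file.path(od, "target_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$enrichment, file.path(od, "lfq_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  params <- config
  params$sim <- unclass(config$sim)
  params$out_dir <- NULL
  manifest <- list(
    package = "chirptools",
    version = as.character(utils::packageVersion("chirptools")),
    r_version = R.version.string,
    parameters = unclass(params),
    n_consensus = nrow(res$chain$consensus),
    n_retained = nrow(res$chain$retained),
    n_removed = nrow(res$chain$removed))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(od)
}
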