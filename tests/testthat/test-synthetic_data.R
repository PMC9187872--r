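test_that("generators are pure functions of the config", {
  cfg <- simulation_config(seed = 5L, chrom_length = 20000L,
                           n_genes = 6L, n_sites = 3L,
                           n_contaminants = 1L, n_expr_genes = 200L,
                           n_targets = 10L, n_proteins = 50L,
                           n_enriched = 5L)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$assembly$sequence),
                   as.character(g2$assembly$sequence))
  expect_identical(g1$genes$genes, g2$genes$genes)
  c1 <- simulate_chirp(cfg, g1); c2 <- simulate_chirp(cfg, g2)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$tracks[[2L]]$odd$segments,
                   c2$tracks[[2L]]$odd$segments)
  e1 <- simulate_expression(cfg); e2 <- simulate_expression(cfg)
  expect_identical(e1$expr, e2$expr)
  l1 <- simulate_lfq(cfg); l2 <- simulate_lfq(cfg)
  expect_identical(l1$intensity, l2$intensity)
})

test_that("simulated genome: composition, gene geometry, file output", {
  cfg <- simulation_config(seed = 2L, chrom_length = 50000L,
                           n_genes = 10L)
  g <- simulate_genome(cfg)
  # base composition ~ uniform within 3 binomial SE
  freq <- genome_background(g$assembly)
  n <- sum(g$assembly$seqlengths)
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 3 * se + 0.002))
  # genes never overlap (interval sweep per chromosome)
  gd <- g$genes$genes
  for (ch in unique(gd$chrom)) {
    x <- gd[gd$chrom == ch, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1L)
      expect_true(all(x$start[-1L] >= x$end[-nrow(x)]))
  }
  # exons inside their gene
  ex <- merge(g$genes$exons, gd, by = "gene_id")
  expect_true(all(ex$start.x >= ex$start.y & ex$end.x <= ex$end.y))
  # written files read back as equivalent objects
  dir <- withr::local_tempdir()
  paths <- write_genome_files(g, dir)
  asm2 <- read_genome_fasta(paths[["fasta"]])
  expect_identical(as.character(asm2$sequence),
                   as.character(g$assembly$sequence))
  gm2 <- read_gtf_genes(paths[["gtf"]])
  expect_equal(gm2$genes$start, gd$start)
  expect_equal(gm2$genes$tss, gd$tss)
  rp2 <- read_bed_repeats(paths[["repeats"]])
  expect_equal(rp2$class, g$repeats$class)
})

test_that("negative control: no planted sites, no consensus calls", {
  cfg <- simulation_config(seed = 3L, chrom_length = 40000L,
                           n_genes = 5L, n_sites = 0L,
                           n_contaminants = 0L)
  g <- simulate_genome(cfg)
  ch <- simulate_chirp(cfg, g)
  chain <- run_chirp_consensus(ch$tracks, ch$assembly, ch$probes,
                               pipeline_config(seed = 3L, sim = cfg))
  expect_equal(nrow(chain$consensus), 0L)
  expect_equal(nrow(chain$retained), 0L)
})

test_that("contaminant loci carry a verbatim probe copy, real sites do not", {
  cfg <- simulation_config(seed = 4L)
  g <- simulate_genome(cfg)
  ch <- simulate_chirp(cfg, g)
  probes <- c(ch$probes$even, ch$probes$odd)
  contam <- ch$truth[ch$truth$type == "contaminant", ]
  for (i in seq_len(nrow(contam))) {
    s <- assembly_sequence(ch$assembly, contam$chrom[i], contam$start[i],
                           contam$end[i])
    expect_true(any(vapply(probes, grepl, TRUE, x = s, fixed = TRUE)))
  }
  # probe filter separates the two classes exactly (truth comparison)
  dec <- scan_and_filter(ch$truth, ch$assembly, probes)
  expect_equal(sort(dec$removed$start), sort(contam$start))
  expect_true(all(dec$retained$type == "real"))
})

test_that("expression generator: DE calibration and planted recovery", {
  cfg <- simulation_config(seed = 6L)
  ex <- simulate_expression(cfg)
  null_stat <- ex$de$stat[ex$de$gene_id %in%
                            ex$truth$gene_id[ex$truth$regulation == "null"]]
  nominal <- 2 * pnorm(-2)
  se <- sqrt(nominal * (1 - nominal) / length(null_stat))
  expect_lt(abs(mean(abs(null_stat) > 2) - nominal), 3 * se)
  # planted four-fold genes reach their status at the default gates
  d5 <- ex$de[ex$de$day == 5L, ]
  st <- de_status(d5$stat, d5$fdr)
  up_truth <- ex$truth$gene_id[ex$truth$regulation == "up"]
  expect_gte(mean(st[match(up_truth, d5$gene_id)] == "up"), 0.95)
  # metadata covers the full 2 x 2 x 4 design uniquely
  expect_equal(nrow(unique(ex$meta[, c("condition", "day", "replicate")])),
               16L)
})

test_that("LFQ generator: flags dropped, exclusives tagged", {
  cfg <- simulation_config(seed = 1L)
  sim <- simulate_lfq(cfg)
  prep <- lfq_preprocess(sim$intensity, sim$condition, sim$flags)
  flagged <- rownames(sim$flags)[rowSums(sim$flags) > 0]
  expect_equal(sort(prep$dropped_flagged), sort(flagged))
  expect_false(any(flagged %in% rownames(prep$log2)))
  # exclusive tags match the observed missingness pattern
  lm <- log2(sim$intensity[rownames(prep$log2), , drop = FALSE])
  n_fl <- rowSums(!is.na(lm[, sim$condition == "fl", drop = FALSE]))
  n_mut <- rowSums(!is.na(lm[, sim$condition == "mut", drop = FALSE]))
  expect_equal(unname(prep$exclusive),
               unname((n_fl == 5L & n_mut == 0L) |
                        (n_mut == 5L & n_fl == 0L)))
  expect_gte(sum(prep$exclusive), 1L)
  # planted recovery through the full statistical chain
  imp <- lfq_impute(prep$log2, seed = 42)
  enr <- permutation_fdr(imp, prep$condition, numerator = "mut",
                         denominator = "fl")
  cls <- classify_enrichment(enr$log2_ratio, enr$neg_log10_p)
  planted <- sim$truth$protein[sim$truth$enriched]
  expect_gte(sum(enr$protein %in% planted & cls == "denominator") /
               length(planted), 0.8)
})
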