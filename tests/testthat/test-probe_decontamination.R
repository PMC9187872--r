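test_that("probe matrix construction follows the smoothing formula", {
  m <- build_probe_matrix("AAAA", pseudo = 0.01)
  # matching base: (1 - 0.01) + 0.01 * 0.25 = 0.9925
  expect_equal(unname(m$freqs["A", 1L]), 0.9925)
  expect_equal(unname(m$scores["A", 1L]), log2(0.9925 / 0.25))
  expect_equal(unname(m$scores["C", 2L]), log2(0.0025 / 0.25))
  expect_equal(colSums(m$freqs), rep(1, 4))

  # pseudo -> 0 limit: 2 bits per matching position under uniform bg
  m2 <- build_probe_matrix("ACGT", pseudo = 1e-9)
  expect_equal(unname(m2$scores["C", 2L]), 2, tolerance = 1e-6)

  m20 <- build_probe_matrix(strrep("ACGTA", 4L))
  expect_equal(dim(m20$scores), c(4L, 20L))
  expect_equal(colSums(m20$freqs), rep(1, 20))

  expect_error(build_probe_matrix("ACGN"), "outside A/C/G/T")
  expect_error(build_probe_matrix("ACGT", pseudo = 0.7), "pseudo")
  expect_error(build_probe_matrix("ACG"), "at least 4")
})

test_that("exact p-value DP equals exhaustive enumeration for L <= 6", {
  set.seed(13)
  g <- 1 / 1000
  for (L in 4:6) {
    for (rep in 1:3) {
      probe <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
      bg <- if (rep == 1L) NULL else {
        p <- stats::runif(4, 0.5, 2); stats::setNames(p / sum(p),
                                                      c("A", "C", "G", "T"))
      }
      m <- build_probe_matrix(probe, background = bg)
      tab <- exact_pvalue_table(m, granularity = g)
      oracle <- enum_tail(m, g)
      # probe the table at every achievable word score plus the extremes
      k <- round(m$scores / g)
      words <- as.matrix(expand.grid(rep(list(1:4), L)))
      ks <- unique(vapply(seq_len(nrow(words)), function(w)
        sum(k[cbind(words[w, ], seq_len(L))]), 0))
      dp_p <- pvalue_lookup(tab, ks * g)
      enum_p <- vapply(ks, oracle, 0)
      expect_equal(dp_p, enum_p, tolerance = 1e-12)
      # total probability at the minimum score
      expect_equal(pvalue_lookup(tab, tab$kmin * g), 1)
    }
  }
})

test_that("perfect-match p-value matches the enumeration value (~0.25^L)", {
  g <- 1 / 1000
  m <- build_probe_matrix("ACGTAC")
  tab <- exact_pvalue_table(m, granularity = g)
  oracle <- enum_tail(m, g)
  kbest <- sum(apply(round(m$scores / g), 2, max))  # top discretised bin
  p <- pvalue_lookup(tab, kbest * g)
  expect_equal(p, oracle(kbest), tolerance = 1e-12)
  expect_equal(p, 0.25^6, tolerance = 1e-12)
  # a raw (undiscretised) perfect-match score maps into the same tail
  expect_equal(pvalue_lookup(tab, sum(apply(m$scores, 2, max))), p,
               tolerance = 1e-12)
})

test_that("DP tail agrees with Monte-Carlo sampling for a 20-nt probe", {
  set.seed(99)
  probe <- strrep("ACGTG", 4L)
  m <- build_probe_matrix(probe)
  tab <- exact_pvalue_table(m)
  n <- 1e6
  draws <- matrix(sample.int(4L, n * 20L, replace = TRUE), n, 20L)
  sc <- numeric(n)
  for (j in 1:20) sc <- sc + m$scores[cbind(draws[, j], j)]
  # compare at a tail point with enough mass to estimate
  s <- stats::quantile(sc, 0.999)
  phat <- mean(sc >= s)
  p <- pvalue_lookup(tab, s)
  se <- sqrt(phat * (1 - phat) / n)
  expect_lt(abs(p - phat), 3 * se + 1e-6)
})

test_that("scan_and_filter removes probe-matching sites on either strand", {
  set.seed(7)
  asm <- tiny_assembly(20000L, with_seq = TRUE)
  probe <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                 collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe)))
  seqs <- as.character(asm$sequence)
  substr(seqs[["chr1"]], 1001L, 1020L) <- probe          # forward copy
  substr(seqs[["chr1"]], 5001L, 5020L) <- rc             # revcomp copy
  asm <- genome_assembly(asm$seqlengths, Biostrings::DNAStringSet(seqs))

  sites <- data.frame(chrom = "chr1",
                      start = c(900L, 4900L, 12000L),
                      end = c(1200L, 5200L, 12300L),
                      summit = c(1010L, 5010L, 12150L))
  res <- scan_and_filter(sites, asm, c(p1 = probe))
  expect_equal(nrow(res$removed), 2L)
  expect_equal(res$removed$start, c(900L, 4900L))
  expect_equal(nrow(res$retained), 1L)
  expect_true(all(res$matches$pvalue < 1e-8))
  # the verbatim-match p-value is far below the cutoff (~0.25^20)
  expect_lt(min(res$matches$pvalue), 1e-10)
})

test_that("strand symmetry and cutoff anti-monotonicity", {
  set.seed(21)
  probe <- paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE),
                 collapse = "")
  m <- build_probe_matrix(probe)
  tab <- exact_pvalue_table(m)
  seq <- paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE),
               collapse = "")
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  expect_equal(min(scan_sequence(m, tab, seq)$pvalue),
               min(scan_sequence(m, tab, rcseq)$pvalue))

  # stricter cutoff never removes more sites
  asm <- tiny_assembly(10000L, with_seq = TRUE)
  sites <- data.frame(chrom = "chr1",
                      start = seq(0L, 9000L, by = 1000L))
  sites$end <- sites$start + 500L
  sites$summit <- sites$start + 250L
  n_removed <- vapply(c(1e-2, 1e-4, 1e-8), function(cut)
    nrow(scan_and_filter(sites, asm, c(p = probe),
                         p_cutoff = cut)$removed), 0)
  expect_true(all(diff(n_removed) <= 0))
})
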