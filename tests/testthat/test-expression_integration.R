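test_that("de_status implements the FDR and stat gates exactly", {
  expect_equal(de_status(2.5, 0.01), "up")
  expect_equal(de_status(5, 0.2), "unchanged")     # fails the FDR gate
  expect_equal(de_status(-2.0, 0.04), "unchanged") # strict inequality
  expect_equal(de_status(-2.001, 0.04), "down")
  expect_equal(de_status(2.0, 0.04), "unchanged")
  expect_equal(de_status(0.5, 0.001), "unchanged")
  expect_equal(de_status(3, 0.05), "unchanged")    # fdr boundary strict
  # row-order invariance of the tally
  set.seed(3)
  stat <- rnorm(500, sd = 3); fdr <- runif(500)
  o <- sample.int(500)
  expect_equal(table(de_status(stat, fdr)),
               table(de_status(stat[o], fdr[o])))
})

test_that("normalisation to control day 5", {
  meta <- toy_meta()
  set.seed(11)
  m <- matrix(rlnorm(3 * 16, 3, 1), 3, 16,
              dimnames = list(c("a", "b", "c"), meta$sample))
  res <- normalize_to_control_day5(m, meta)
  con5 <- meta$sample[meta$condition == "CON" & meta$day == 5]
  expect_equal(unname(rowMeans(res$matrix[, con5])), rep(1, 3))
  # hand-computed ratios
  expect_equal(res$matrix, m / rowMeans(m[, con5]))
  # a gene doubled in KD day 7 relative to control day 5
  m2 <- m
  m2["a", ] <- 10
  kd7 <- meta$sample[meta$condition == "KD" & meta$day == 7]
  m2["a", kd7] <- 20
  expect_equal(unname(normalize_to_control_day5(m2, meta)$matrix["a", kd7]),
               rep(2, 4))
  # non-positive control mean is flagged and excluded
  m3 <- m; m3["b", con5] <- 0
  res3 <- normalize_to_control_day5(m3, meta)
  expect_equal(res3$excluded, "b")
  expect_false("b" %in% rownames(res3$matrix))
  expect_error(normalize_to_control_day5(m[, kd7], meta), "CON day-5")
})

test_that("two-cluster structure recovers planted opposite effects", {
  meta <- toy_meta()
  set.seed(21)
  kd <- meta$condition == "KD"
  base <- 100
  mk_gene <- function(fc_kd)
    base * 2^(ifelse(kd, fc_kd, 0)) * rlnorm(16, 0, 0.1)
  m <- rbind(t(sapply(rep(-2, 6), mk_gene)),   # down-regulated group
             t(sapply(rep(2, 6), mk_gene)))    # up-regulated group
  rownames(m) <- sprintf("g%02d", 1:12)
  colnames(m) <- meta$sample
  cl <- cluster_targets(m, meta)
  expect_equal(cl$cluster[1:6], rep("I", 6))   # lower KD/CON ratio
  expect_equal(cl$cluster[7:12], rep("II", 6))
  # duplicate rows get identical labels
  m2 <- rbind(m, dup = m[1, ])
  cl2 <- cluster_targets(m2, meta)
  expect_equal(cl2$cluster[cl2$gene_id == "dup"],
               cl2$cluster[cl2$gene_id == "g01"])
  # gene-permutation invariance (labels fixed by the ratio rule)
  o <- sample.int(12)
  cl3 <- cluster_targets(m[o, ], meta)
  expect_equal(cl3$cluster[match(cl$gene_id, cl3$gene_id)], cl$cluster)
  expect_error(cluster_targets(matrix(1, 3, 16,
                                      dimnames = list(letters[1:3],
                                                      meta$sample)), meta),
               "constant")
  expect_error(cluster_targets(m[1, , drop = FALSE], meta), "at least 2")
})

test_that("lncRNA-target correlation matches the textbook formula", {
  meta <- toy_meta()
  set.seed(31)
  lnc <- rlnorm(16, 3, 0.5)
  m <- rbind(lnc = lnc, t1 = 2 * lnc, t2 = max(lnc) + 1 - lnc,
             t3 = rlnorm(16, 2, 0.3), flat = rep(5, 16))
  colnames(m) <- meta$sample
  r <- lnc_target_correlation(m, meta, "lnc", day = 5)
  expect_equal(unname(r["t1"]), 1)
  expect_equal(unname(r["t2"]), -1)
  d5 <- meta$sample[meta$day == 5]
  expect_equal(unname(r["t3"]), cor(lnc[match(d5, colnames(m))],
                                    m["t3", d5]))
  expect_true(is.na(r["flat"]))
  expect_error(lnc_target_correlation(m, meta, "absent", day = 5),
               "not in matrix")
})

test_that("candidate screen applies the three criteria", {
  tissues <- c(cortex = TRUE, hippocampus = TRUE, liver = FALSE,
               heart = FALSE)
  te <- rbind(
    neural_up = c(10, 8, 0.1, 0.2),    # neural only
    in_liver = c(10, 8, 9, 0.2),       # criterion 1 fails
    neural_flat = c(5, 5, 0.1, 0.1),   # criterion 2 will fail
    not_conserved = c(10, 8, 0.1, 0.2))
  colnames(te) <- names(tissues)
  set.seed(41)
  before <- matrix(rnorm(4 * 6, 1, 0.1), 4, 6,
                   dimnames = list(rownames(te), NULL))
  after <- before + 0.05 * matrix(rnorm(24), 4, 6)
  after["neural_up", ] <- before["neural_up", ] + 3
  after["in_liver", ] <- before["in_liver", ] + 3
  after["not_conserved", ] <- before["not_conserved", ] - 3
  conserved <- c(TRUE, TRUE, TRUE, FALSE)
  res <- screen_candidates(te, tissues, before, after, conserved)
  expect_equal(res$pass,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$direction[1L], "increase")
  expect_true(res$neural_only[1L] && !res$neural_only[2L])
  expect_error(screen_candidates(te, tissues[1:2], before, after,
                                 conserved), "label")
})

test_that("planted coupling signs are recovered by the correlation", {
  cfg <- simulation_config(seed = 1L)
  ex <- simulate_expression(cfg)
  ok <- 0L; tot <- 0L
  for (d in c(5L, 7L)) {
    r <- lnc_target_correlation(ex$expr, ex$meta, ex$lnc_gene,
                                ex$target_genes, day = d)
    ts <- ex$truth[[paste0("coupling", d)]][
      match(ex$target_genes, ex$truth$gene_id)]
    ok <- ok + sum(sign(r) == ts); tot <- tot + length(r)
  }
  expect_gte(ok / tot, 0.95)
})
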