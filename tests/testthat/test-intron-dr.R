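dr_toy_sim <- function(seed = 8L, strains = NULL) {
  sc <- simulation_scenario(seed = seed, n_genes = 150L,
                            intron_probability = 1, strains = strains)
  ann <- simulate_annotation(sc)
  list(sc = sc, ann = ann, sim = simulate_counts(sc, ann))
}

test_that("dr_test demands matching library sets and borrowed factors", {
  s <- dr_toy_sim()
  sf_bad <- setNames(rep(1, 3), paste0("x", 1:3))
  expect_error(dr_test(s$sim$intron_se, sf_bad, "ku70", "upf1"),
               "size factors")
  sf <- size_factors(counts_of_se(s$sim$gene_se))
  res <- dr_test(s$sim$intron_se, sf, "ku70", "upf1")
  expect_true(all(c("gene_id", "direction") %in% names(res)))
  sig <- res$status %in% c("up", "down")
  expect_true(all(res$direction[sig & res$log2fc > 0] == "more_retained"))
  expect_true(all(is.na(res$direction[!sig])))
})

test_that("identical intron counts across libraries are never called DR", {
  s <- dr_toy_sim()
  m <- counts_of_se(s$sim$intron_se)
  m[] <- rep(200L, length(m))
  se <- count_matrix(m, lengths = rep(100L, nrow(m)),
                     meta = as.data.frame(SummarizedExperiment::colData(
                       s$sim$intron_se)))
  sf <- setNames(rep(1, ncol(m)), colnames(m))
  res <- dr_test(se, sf, "ku70", "upf1")
  expect_true(all(res$status == "ns"))
  expect_true(all(abs(res$log2fc) < 1e-6))
})

test_that("an 8x retention shift is detected as more_retained", {
  s <- dr_toy_sim(seed = 9L, strains = list(
    strain_spec("ku70"),
    strain_spec("upf1", dr_fraction = 0.3, dr_multiplier = 8,
                dr_direction = "more")))
  dr <- dr_analysis(s$sim$intron_se, s$sim$gene_se, "ku70")$upf1
  truth <- s$sim$truth$dr_introns$upf1$intron_id
  called <- dr$feature_id[dr$status %in% c("up", "down")]
  expect_gt(mean(truth %in% called), 0.8)
  expect_true(all(dr$direction[dr$feature_id %in% intersect(called, truth)] ==
                    "more_retained"))
})

test_that("gene-derived factors recover a global intron-mass shift that subset factors absorb", {
  s <- dr_toy_sim(seed = 10L, strains = list(
    strain_spec("ku70"),
    strain_spec("shift", global_retention_multiplier = 2)))
  gene_sf <- size_factors(counts_of_se(s$sim$gene_se))
  res_gene <- dr_test(s$sim$intron_se, gene_sf, "ku70", "shift")
  intron_sf <- size_factors(counts_of_se(s$sim$intron_se))
  res_sub <- dr_test(s$sim$intron_se, intron_sf, "ku70", "shift")
  # the contract is about normalization bias: with gene-derived factors the
  # estimates center on the true +1 log2 shift; subset-derived factors absorb
  # the shift into the normalization and the estimates center near 0
  ok <- res_gene$status != "filtered"
  bias_gene <- abs(mean(res_gene$log2fc[ok]) - 1)
  bias_sub <- abs(mean(res_sub$log2fc[res_sub$status != "filtered"]) - 1)
  expect_lt(bias_gene, 0.2)
  expect_gt(bias_sub, bias_gene + 0.3)
})

test_that("dr_test is invariant to jointly rescaling a library's gene and intron counts", {
  s <- dr_toy_sim(seed = 11L)
  gm <- counts_of_se(s$sim$gene_se)
  im <- counts_of_se(s$sim$intron_se)
  meta <- as.data.frame(SummarizedExperiment::colData(s$sim$gene_se))
  r1 <- dr_test(s$sim$intron_se, size_factors(gm), "ku70", "y14")
  gm2 <- gm; im2 <- im
  gm2[, 4] <- gm2[, 4] * 2L
  im2[, 4] <- im2[, 4] * 2L
  ise2 <- count_matrix(im2, lengths = rep(100L, nrow(im2)), meta = meta)
  SummarizedExperiment::rowData(ise2)$gene_id <-
    SummarizedExperiment::rowData(s$sim$intron_se)$gene_id
  r2 <- dr_test(ise2, size_factors(gm2), "ku70", "y14")
  common <- intersect(r1$feature_id[!is.na(r1$log2fc)],
                      r2$feature_id[!is.na(r2$log2fc)])
  expect_equal(r2$log2fc[match(common, r2$feature_id)],
               r1$log2fc[match(common, r1$feature_id)], tolerance = 0.02)
})

test_that("union across mutants is the set union of significant introns", {
  mk <- function(ids, sig_ids, fc) {
    data.frame(feature_id = ids, log2fc = fc,
               padj = ifelse(ids %in% sig_ids, 1e-6, 0.5),
               status = factor(ifelse(ids %in% sig_ids,
                                      ifelse(fc > 0, "up", "down"), "ns"),
                               levels = c("up", "down", "ns", "filtered")))
  }
  ids <- c("a", "b", "c", "d")
  u <- union_dr(list(m1 = mk(ids, c("a", "b"), c(2, 2, 0, 0)),
                     m2 = mk(ids, c("b", "c"), c(0, 3, -2, 0))))
  expect_setequal(u$introns, c("a", "b", "c"))
  expect_equal(dim(u$fc), c(3L, 2L))
  expect_equal(u$fc["c", "m2"], -2)

  none <- union_dr(list(m1 = mk(ids, character(0), rep(0, 4))))
  expect_equal(length(none$introns), 0L)

  only2 <- union_dr(list(m1 = mk(ids, character(0), rep(0, 4)),
                         m2 = mk(ids, "d", c(0, 0, 0, 2))))
  expect_equal(only2$introns, "d")
})

test_that("restriction to non-DE host genes follows the truth table", {
  introns <- sprintf("i%02d", 1:12)
  hosts <- sprintf("g%02d", 1:12)
  dr <- data.frame(
    feature_id = introns, gene_id = hosts, log2fc = 2,
    padj = c(rep(1e-6, 10), 0.7, 0.7),
    status = factor(c(rep("up", 10), "ns", "ns"),
                    levels = c("up", "down", "ns", "filtered")))
  gene_de <- data.frame(
    feature_id = hosts,
    status = factor(c(rep("up", 3), "down", rep("ns", 7), "filtered"),
                    levels = c("up", "down", "ns", "filtered")))
  kept <- restrict_to_nonde(dr, gene_de)
  # 10 significant introns, 4 in DE genes -> 6 survive
  expect_equal(nrow(kept), 6L)
  expect_setequal(kept$feature_id, sprintf("i%02d", 5:10))

  dr_bad <- dr
  dr_bad$gene_id[1] <- "unknown_gene"
  expect_error(restrict_to_nonde(dr_bad, gene_de), "absent")
})

test_that("introns of filtered host genes are excluded from the restricted set", {
  dr <- data.frame(feature_id = "i1", gene_id = "g1", log2fc = 3, padj = 1e-9,
                   status = factor("up", levels = c("up", "down", "ns",
                                                    "filtered")))
  gene_de <- data.frame(feature_id = "g1",
                        status = factor("filtered",
                                        levels = c("up", "down", "ns",
                                                   "filtered")))
  expect_equal(nrow(restrict_to_nonde(dr, gene_de)), 0L)
})

test_that("fold-change clustering uses Euclidean distance with complete linkage", {
  fc <- rbind(a = c(0, 0), b = c(0, 3), c = c(4, 0))
  colnames(fc) <- c("m1", "m2")
  cl <- cluster_fold_changes(fc)
  # first merge is the closest pair: a-b at distance 3
  expect_setequal(rownames(fc)[-cl$row_hclust$merge[1, ]], c("a", "b"))
  expect_equal(cl$row_hclust$height[1], 3)

  dup <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  colnames(dup) <- c("m1", "m2")
  cl2 <- cluster_fold_changes(dup)
  expect_equal(cl2$row_hclust$height[1], 0)

  # sign-flipped mutant profiles merge last in the column dendrogram
  set.seed(2)
  prof <- matrix(rnorm(20), 10)
  fc3 <- cbind(m1 = prof[, 1], m2 = prof[, 1] + 0.1 * prof[, 2],
               m3 = -prof[, 1])
  rownames(fc3) <- paste0("i", 1:10)
  cl3 <- cluster_fold_changes(fc3)
  expect_equal(max(cl3$col_hclust$height),
               as.matrix(dist(t(fc3)))["m3", "m1"], tolerance = 0.5)
  expect_equal(cl3$col_hclust$merge[2, 1], -match("m3", colnames(fc3)))
})

test_that("clustering is equivariant under row permutation", {
  set.seed(14)
  fc <- matrix(rnorm(40), 10, dimnames = list(paste0("i", 1:10),
                                              paste0("m", 1:4)))
  cl <- cluster_fold_changes(fc)
  perm <- sample(10)
  cl_p <- cluster_fold_changes(fc[perm, ])
  expect_equal(cl_p$row_order, cl$row_order)
  expect_equal(cl_p$row_hclust$height, cl$row_hclust$height)
})

test_that("correspondence-analysis clustering groups libraries by strain", {
  # strain effects far above replicate noise: each strain's replicates
  # must form one cluster
  strains <- list(
    strain_spec("ku70"),
    strain_spec("upf1", de_fraction = 0.3),
    strain_spec("upf2", de_fraction = 0.3),
    strain_spec("mago", de_fraction = 0.3),
    strain_spec("y14", de_fraction = 0.3))
  sc <- simulation_scenario(seed = 19L, n_genes = 300L, strains = strains)
  ann <- simulate_annotation(sc)
  sim <- simulate_counts(sc, ann)
  co <- coa_library_clustering(sim$gene_se)
  grp <- cutree(co$hclust, k = 5)
  strain <- SummarizedExperiment::colData(sim$gene_se)$strain
  # within a strain all replicates share a cluster label
  expect_true(all(tapply(grp, strain, function(x) length(unique(x))) == 1))

  # duplicated libraries have zero distance
  m <- counts_of_se(sim$gene_se)
  dup <- cbind(m, dupA = m[, 1])
  co2 <- coa_library_clustering(dup)
  d <- as.matrix(co2$dist)
  expect_equal(d[colnames(m)[1], "dupA"], 0, tolerance = 1e-10)

  # identical columns everywhere: all distances 0
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(max(as.matrix(coa_library_clustering(same)$dist)), 0,
               tolerance = 1e-10)
})
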