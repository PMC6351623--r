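test_that("low-count filter removes features at or below the RPK cutoff in enough libraries", {
  n <- 15L
  mk <- function(rpk_rows) {
    # features of length 1000 bp so counts equal RPK
    m <- do.call(rbind, rpk_rows)
    rownames(m) <- paste0("f", seq_along(rpk_rows))
    colnames(m) <- paste0("lib", seq_len(n))
    toy_se(m, lengths = rep(1000L, length(rpk_rows)))
  }
  se <- mk(list(
    rep(0L, n),                       # all zero: removed
    rep(41L, n),                      # just above everywhere: kept
    c(rep(40L, 10), rep(100L, 5)),    # exactly 40 in 10 of 15: removed
    c(rep(40L, 9), rep(100L, 6))))    # exactly 40 in only 9: kept
  flt <- low_count_filter(se, filter_spec(rpk_threshold = 40,
                                          min_low_libraries = 10))
  expect_setequal(flt$removed, c("f1", "f3"))
  expect_setequal(flt$kept, c("f2", "f4"))

  # default minimum is ceiling(2/3 n): 10 when n = 15
  flt2 <- low_count_filter(se, filter_spec())
  expect_equal(flt2$removed, flt$removed)
})

test_that("median-of-ratios size factors match the definition", {
  m <- matrix(rpois(60, 50) + 1L, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("l", 1:6)))
  # identical libraries: all factors 1
  ident <- m[, c(1, 1, 1)]
  colnames(ident) <- paste0("l", 1:3)
  expect_equal(unname(size_factors(ident)), rep(1, 3), ignore_attr = TRUE)

  # doubling one library doubles its factor relative to the other
  two <- cbind(l1 = m[, 1], l2 = 2L * m[, 1])
  s <- size_factors(two)
  expect_equal(unname(s), c(2^-0.5, 2^0.5), ignore_attr = TRUE)

  # single library: factor 1
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1,
               ignore_attr = TRUE)

  # geometric mean is 1 and ratios agree with the DESeq2 reference
  s_all <- size_factors(m)
  expect_equal(exp(mean(log(s_all))), 1, ignore_attr = TRUE)
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(s_all / s_all[1]), unname(ref / ref[1]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("size factors fall back to totals when no feature is positive everywhere", {
  m <- matrix(c(5L, 0L, 0L, 7L), 2, dimnames = list(c("a", "b"), c("l1", "l2")))
  expect_warning(s <- size_factors(m), "falling back")
  expect_equal(attr(s, "method"), "total_count")
  expect_equal(unname(s), c(5, 7) / sqrt(35), ignore_attr = TRUE)
})

test_that("method-of-moments dispersion follows the pooled formula", {
  # pooled within-group variance 600 at normalized mean 100 -> alpha 0.05
  x <- c(80, 100, 120)  # mean 100, var 400
  y <- c(100 - sqrt(800), 100, 100 + sqrt(800))  # mean 100, var 800
  k <- rbind(f1 = c(x, y))
  sf <- rep(1, 6); grp <- rep(c("a", "b"), each = 3)
  a <- estimate_dispersion(round(k), sf, grp)
  # pooled var = (400 + 800)/2 = 600 (up to rounding of counts)
  expect_equal(unname(a), (600 - 100) / 100^2, tolerance = 0.02)

  # Poisson-like and constant features sit at the floor
  pois <- rbind(f1 = c(99, 100, 101, 99, 100, 101))
  expect_equal(unname(estimate_dispersion(pois, sf, grp)), 1e-8)
  const <- rbind(f1 = rep(50, 6))
  expect_equal(unname(estimate_dispersion(const, sf, grp)), 1e-8)
})

test_that("NB Wald test recovers null and strong-effect cases", {
  sf <- setNames(rep(1, 6), paste0("l", 1:6))
  grp <- rep(c("ctl", "mut"), each = 3)

  ident <- matrix(rep(c(50L, 60L, 70L), 2), nrow = 1,
                  dimnames = list("f1", names(sf)))
  r <- nb_wald_test(ident, sf, 0.05, grp, "ctl", "mut")
  expect_equal(r$log2fc, 0, tolerance = 1e-6)
  expect_gt(r$pvalue, 0.99)

  quad <- matrix(c(50L, 60L, 70L, 200L, 240L, 280L), nrow = 1,
                 dimnames = list("f1", names(sf)))
  r4 <- nb_wald_test(quad, sf, 1e-6, grp, "ctl", "mut")
  expect_equal(r4$log2fc, 2, tolerance = 1e-4)

  zero <- matrix(0L, 1, 6, dimnames = list("f1", names(sf)))
  rz <- nb_wald_test(zero, sf, 0.05, grp, "ctl", "mut")
  expect_equal(rz$log2fc, 0)
  expect_equal(rz$pvalue, 1)
})

test_that("the IRLS fit matches an independent NB GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(31)
  sf <- setNames(runif(6, 0.7, 1.4), paste0("l", 1:6))
  grp <- rep(c("ctl", "mut"), each = 3)
  x <- as.numeric(grp == "mut")
  alpha <- 0.08
  for (i in 1:20) {
    k <- rnbinom(6, mu = sf * exp(4 + 1.2 * x), size = 1 / alpha)
    if (any(tapply(k, grp, sum) == 0)) next
    m <- matrix(k, 1, dimnames = list("f", names(sf)))
    ours <- nb_wald_test(m, sf, alpha, grp, "ctl", "mut")
    ref <- glm(k ~ x + offset(log(sf)),
               family = MASS::negative.binomial(theta = 1 / alpha))
    expect_equal(ours$log2fc, unname(coef(ref)[2]) / log(2), tolerance = 1e-4)
    # fixed-dispersion Wald SE: compare against the GLM at dispersion 1
    ref_se <- summary(ref, dispersion = 1)$coefficients[2, 2] / log(2)
    expect_equal(ours$lfcSE, ref_se, tolerance = 1e-3)
  }
})

test_that("fold-change estimates are invariant to rescaling a library's counts", {
  set.seed(41)
  m <- matrix(rnbinom(600, mu = 80, size = 10), nrow = 100,
              dimnames = list(paste0("f", 1:100), paste0("l", 1:6)))
  grp <- rep(c("ctl", "mut"), each = 3)
  s1 <- size_factors(m)
  r1 <- nb_wald_test(m, s1, 0.1, grp, "ctl", "mut")
  m2 <- m
  m2[, 2] <- m2[, 2] * 3L
  s2 <- size_factors(m2)
  # scaled library's factor grows by 3 (ratios preserved after rescale)
  expect_equal(unname(s2[2] / s2[1]), unname(3 * s1[2] / s1[1]),
               tolerance = 1e-10)
  r2 <- nb_wald_test(m2, s2, 0.1, grp, "ctl", "mut")
  # NB weights depend on the absolute counts, so the estimates are invariant
  # only up to a small likelihood-weighting effect
  expect_lt(max(abs(r2$log2fc - r1$log2fc)), 0.05)
})

test_that("BH adjustment equals brute-force step-up on short vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(17)
  for (n in 1:6) {
    for (rep in 1:30) {
      p <- round(runif(n), 3)
      expect_equal(bh_adjust(p), brute_bh(p), info = paste(n, rep))
    }
  }
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("classification applies inclusive fold-change and strict p cutoffs", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    log2fc = c(2, 1.5, -3, -1.5, 0.2),
    padj = c(1e-5, 1e-5, 0.5, 1e-4, 1e-6))
  cl <- classify_de(res)
  expect_equal(as.character(cl$status), c("up", "up", "ns", "down", "ns"))
  # configurable relaxed threshold
  cl1 <- classify_de(transform(res, log2fc = c(1.2, 1.0, -1.1, -0.9, 0.2)),
                     lfc_threshold = 1)
  expect_equal(as.character(cl1$status), c("up", "up", "ns", "ns", "ns"))
})

test_that("classification is monotone in padj and |log2fc|", {
  set.seed(23)
  # half the cases drawn from the significant region so the property is
  # exercised on calls that can actually be lost
  fc <- c(runif(100, -4, 4), sample(c(-1, 1), 100, TRUE) * runif(100, 1.5, 4))
  p <- c(runif(100), runif(100, 0, 1e-3))
  moved <- 0L
  for (i in seq_along(fc)) {
    s0 <- classify_de(data.frame(feature_id = "f", log2fc = fc[i],
                                 padj = p[i]))$status
    s1 <- classify_de(data.frame(feature_id = "f", log2fc = fc[i] * 1.5,
                                 padj = p[i] / 2))$status
    if (s0 %in% c("up", "down") && s1 != s0) moved <- moved + 1L
  }
  expect_identical(moved, 0L)
})

test_that("de_analysis carries filtered features and classifies the rest", {
  sc <- simulation_scenario(seed = 3L, n_genes = 120L)
  ann <- simulate_annotation(sc)
  sim <- simulate_counts(sc, ann)
  de <- de_analysis(sim$gene_se, "ku70", "y14")
  expect_setequal(de$feature_id, rownames(sim$gene_se))
  expect_true(all(is.na(de$pvalue[de$status == "filtered"])))
  truth <- sim$truth$de_genes$y14
  strong <- truth$gene_id[abs(truth$log2fc) >= 2 &
                            de$status[match(truth$gene_id, de$feature_id)] !=
                            "filtered"]
  called <- de$feature_id[de$status %in% c("up", "down")]
  expect_gt(mean(strong %in% called), 0.5)
  # direction agrees with the simulated sign for every correctly called gene
  hit <- intersect(strong, called)
  sign_true <- sign(truth$log2fc[match(hit, truth$gene_id)])
  sign_est <- sign(de$log2fc[match(hit, de$feature_id)])
  expect_true(all(sign_true == sign_est))
})
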