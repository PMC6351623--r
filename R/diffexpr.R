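#' Low-count filter specification
#'
#' A feature is removed when its RPK is at or below `rpk_threshold` in at
#' least `min_low_libraries` libraries. The default minimum is
#' `ceiling(2/3 * n_libraries)` — 10 of 15 libraries in the five-strain,
#' three-replicate design.
#'
#' @param rpk_threshold RPK cutoff, inclusive (`<=` counts as low).
#' @param min_low_libraries Number of low libraries triggering removal;
#'   `NULL` means `ceiling(2/3 * n)` at filter time.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(rpk_threshold = 40, min_low_libraries = NULL) {
  stopifnot(rpk_threshold >= 0,
            is.null(min_low_libraries) || min_low_libraries >= 1)
  structure(list(rpk_threshold = rpk_threshold,
                 min_low_libraries = min_low_libraries),
            class = "filter_spec")
}

#' Apply the RPK low-count filter
#'
#' @param se Count container (or matrix plus `lengths`).
#' @param spec A [filter_spec()].
#' @param lengths Feature lengths when `se` is a bare matrix.
#' @return List with character vectors `kept` and `removed`.
#' @export
low_count_filter <- function(se, spec = filter_spec(), lengths = NULL) {
  r <- rpk(se, lengths)
  n <- ncol(r)
  min_low <- spec$min_low_libraries
  if (is.null(min_low)) min_low <- ceiling(2 / 3 * n)
  stopifnot(min_low <= n)
  n_low <- rowSums(r <= spec$rpk_threshold)
  removed <- n_low >= min_low
  list(kept = rownames(r)[!removed], removed = rownames(r)[removed])
}

#' Median-of-ratios size factors
#'
#' For each feature with strictly positive counts in every library, the
#' reference is the geometric mean of its counts across libraries; the size
#' factor of library `j` is the median over those features of
#' `count[f, j] / reference[f]`. Factors are rescaled to geometric mean 1, so
#' they are interpretable as relative depths. If no feature is positive
#' everywhere the total-count method is used instead, with a warning.
#'
#' @param counts Integer matrix (features x libraries) or a count container.
#' @param method `"median_of_ratios"` (default) or `"total_count"`.
#' @return Named numeric vector of positive size factors with geometric mean
#'   1; attribute `method` records the method actually used.
#' @export
size_factors <- function(counts, method = c("median_of_ratios", "total_count")) {
  method <- match.arg(method)
  if (methods::is(counts, "SummarizedExperiment")) counts <- counts_of(counts)
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L)
    return(structure(stats::setNames(1, colnames(counts)), method = method))
  if (method == "median_of_ratios") {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) {
      warning("no feature with positive counts in every library; ",
              "falling back to total-count size factors")
      return(size_factors(counts, "total_count"))
    }
    lc <- log(counts[pos, , drop = FALSE])
    lref <- rowMeans(lc)
    s <- apply(lc, 2L, function(x) exp(stats::median(x - lref)))
  } else {
    s <- colSums(counts)
    if (any(s <= 0)) stop("library with zero total count")
  }
  s <- s / exp(mean(log(s)))
  structure(s, method = method)
}

#' Method-of-moments negative-binomial dispersion
#'
#' Counts are first normalized by the size factors; the per-feature dispersion
#' is `(v - m) / m^2` where `m` is the pooled mean of normalized counts and
#' `v` the pooled within-group variance, floored at `1e-8` (Poisson-like or
#' constant features sit at the floor).
#'
#' @param counts Count matrix or container.
#' @param sf Size factors (named as the columns).
#' @param group Group label per library (two groups expected).
#' @return Numeric vector of dispersions, one per feature.
#' @export
estimate_dispersion <- function(counts, sf, group) {
  if (methods::is(counts, "SummarizedExperiment")) counts <- counts_of(counts)
  counts <- as.matrix(counts)
  stopifnot(length(sf) == ncol(counts), length(group) == ncol(counts))
  tab <- table(group)
  if (any(tab < 2L)) stop("need >= 2 replicates per group")
  y <- sweep(counts, 2L, sf, "/")
  groups <- unique(group)
  m <- rowMeans(y)
  ss <- 0
  for (g in groups) {
    yg <- y[, group == g, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
  }
  v <- ss / (ncol(y) - length(groups))
  alpha <- ifelse(m > 0, (v - m) / m^2, 0)
  pmax(alpha, 1e-8)
}

# IRLS fit of a per-feature NB log-link regression with fixed dispersion.
# x is the 0/1 mutant indicator; offset is log size factor.
.nb_irls <- function(k, sf, alpha, x, max_iter = 50L, tol = 1e-8) {
  o <- log(sf)
  X <- cbind(1, x)
  m0 <- mean(k[x == 0] / sf[x == 0])
  m1 <- mean(k[x == 1] / sf[x == 1])
  b <- c(log(max(m0, 1e-3)), log(max(m1, 1e-3)) - log(max(m0, 1e-3)))
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(o + drop(X %*% b), -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - o) + (k - mu) / mu
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    bnew <- tryCatch(drop(solve(XtWX, crossprod(Xw, z))),
                     error = function(e) NULL)
    if (is.null(bnew)) break
    if (max(abs(bnew - b)) < tol) {
      b <- bnew
      converged <- TRUE
      break
    }
    b <- bnew
  }
  se <- if (!is.null(XtWX)) sqrt(diag(solve(XtWX))[2L]) else NA_real_
  list(b = b, se = se, converged = converged)
}

#' Per-feature negative-binomial Wald test
#'
#' Fits, for every feature, a log-link negative-binomial regression of counts
#' on a two-group indicator with the log size factors as offset and the
#' supplied dispersion held fixed, by iteratively reweighted least squares.
#' The log2 fold change is the group coefficient over `log(2)`; the two-sided
#' p-value comes from the Wald statistic under the normal approximation.
#' Features with all-zero counts in both groups return the null result
#' (`log2fc = 0`, `p = 1`); non-convergent fits are flagged and also return
#' `p = 1`.
#'
#' @param counts Count matrix or container (all libraries or just the two
#'   groups; other columns are ignored).
#' @param sf Size factors named by library.
#' @param dispersion Per-feature dispersion (recycled if scalar).
#' @param group Group label per library.
#' @param control,treatment The two levels of `group` to contrast; the fold
#'   change is treatment over control.
#' @return A `data.frame` with `feature_id`, `baseMean` (mean normalized
#'   count over the two groups), `log2fc`, `lfcSE`, `pvalue`, `padj`
#'   (Benjamini-Hochberg), `dispersion`, `converged`.
#' @export
nb_wald_test <- function(counts, sf, dispersion, group, control, treatment) {
  if (methods::is(counts, "SummarizedExperiment")) counts <- counts_of(counts)
  counts <- as.matrix(counts)
  stopifnot(length(sf) == ncol(counts), length(group) == ncol(counts),
            control %in% group, treatment %in% group)
  keep <- group %in% c(control, treatment)
  counts <- counts[, keep, drop = FALSE]
  sf <- sf[keep]
  x <- as.numeric(group[keep] == treatment)
  n <- nrow(counts)
  dispersion <- rep_len(dispersion, n)
  log2fc <- lfcSE <- pvalue <- numeric(n)
  converged <- logical(n)
  baseMean <- rowMeans(sweep(counts, 2L, sf, "/"))
  for (i in seq_len(n)) {
    k <- counts[i, ]
    if (all(k == 0)) {
      log2fc[i] <- 0; lfcSE[i] <- NA_real_; pvalue[i] <- 1
      converged[i] <- TRUE
      next
    }
    fit <- .nb_irls(k, sf, dispersion[i], x)
    converged[i] <- fit$converged
    if (!fit$converged || !is.finite(fit$se) || fit$se <= 0) {
      log2fc[i] <- fit$b[2L] / log(2); lfcSE[i] <- NA_real_; pvalue[i] <- 1
      next
    }
    log2fc[i] <- fit$b[2L] / log(2)
    lfcSE[i] <- fit$se / log(2)
    zstat <- fit$b[2L] / fit$se
    pvalue[i] <- 2 * stats::pnorm(-abs(zstat))
  }
  if (any(!converged))
    message(sum(!converged), " feature(s) did not converge; p set to 1")
  data.frame(feature_id = rownames(counts), baseMean = baseMean,
             log2fc = log2fc, lfcSE = lfcSE, pvalue = pvalue,
             padj = bh_adjust(pvalue), dispersion = dispersion,
             converged = converged, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment with monotonicity enforcement; `padj` always lies in
#' `[p, 1]`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Classify differential features
#'
#' `up` requires `log2fc >= lfc_threshold` and `padj < alpha`; `down` requires
#' `log2fc <= -lfc_threshold` and `padj < alpha`; everything else is `ns`.
#' The fold-change boundary is inclusive. Features listed in `filtered` get
#' status `filtered`.
#'
#' @param results `data.frame` with `log2fc` and `padj` columns.
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1.5; 1 is
#'   the common relaxed alternative).
#' @param alpha Adjusted p-value cutoff (default 0.001).
#' @param filtered Optional character vector of feature ids that failed the
#'   low-count filter.
#' @return `results` with a `status` factor column
#'   (`up`/`down`/`ns`/`filtered`).
#' @export
classify_de <- function(results, lfc_threshold = 1.5, alpha = 0.001,
                        filtered = NULL) {
  status <- rep("ns", nrow(results))
  sig <- !is.na(results$padj) & results$padj < alpha
  status[sig & results$log2fc >= lfc_threshold] <- "up"
  status[sig & results$log2fc <= -lfc_threshold] <- "down"
  if (!is.null(filtered))
    status[results$feature_id %in% filtered] <- "filtered"
  results$status <- factor(status, levels = c("up", "down", "ns", "filtered"))
  results
}

#' Two-group differential expression analysis of a gene count matrix
#'
#' Convenience wrapper chaining the RPK low-count filter, median-of-ratios
#' size factors (estimated on the filtered matrix across all libraries),
#' method-of-moments dispersions, the NB Wald test and classification, for
#' one mutant-versus-control comparison. Each pairwise comparison is fit
#' independently.
#'
#' @param se Gene-level count container with `strain` column metadata.
#' @param control,treatment Strain names to contrast.
#' @param spec [filter_spec()] for the low-count filter.
#' @param lfc_threshold,alpha Passed to [classify_de()].
#' @param sf Optional size factors to use instead of estimating them from
#'   the filtered matrix (see [dr_test()] for the borrowed-normalization
#'   use).
#' @return A classified `data.frame` (see [nb_wald_test()]); features removed
#'   by the filter appear with status `filtered` and `NA` statistics.
#' @export
de_analysis <- function(se, control, treatment, spec = filter_spec(),
                        lfc_threshold = 1.5, alpha = 0.001, sf = NULL) {
  strain <- strains_of(se)
  if (is.null(strain)) stop("count container lacks strain metadata")
  stopifnot(control %in% strain, treatment %in% strain)
  flt <- low_count_filter(se, spec)
  kept <- counts_of(se)[flt$kept, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(kept)
  keep2 <- strain %in% c(control, treatment)
  disp <- estimate_dispersion(kept[, keep2, drop = FALSE], sf[keep2],
                              strain[keep2])
  res <- nb_wald_test(kept, sf, disp, strain, control, treatment)
  if (length(flt$removed)) {
    res <- rbind(res, data.frame(
      feature_id = flt$removed, baseMean = NA_real_, log2fc = NA_real_,
      lfcSE = NA_real_, pvalue = NA_real_, padj = NA_real_,
      dispersion = NA_real_, converged = NA, stringsAsFactors = FALSE))
  }
  classify_de(res, lfc_threshold, alpha, filtered = flt$removed)
}
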