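#' Differential intron retention with borrowed size factors
#'
#' Runs the same filter / dispersion / NB Wald machinery as [de_analysis()]
#' on the intron count matrix, but with the size factors supplied by the
#' caller — typically median-of-ratios factors estimated on the complete
#' gene-level dataset of the same libraries. Reads mapping to introns are a
#' small subset of the total, so normalizing by the depths of the complete
#' dataset is more reliable than re-estimating factors from the intron
#' sub-matrix, where genuine global retention shifts would be absorbed into
#' the factors. The factors are never re-estimated here.
#'
#' @param intron_se Intron count container; rowData may carry `gene_id`
#'   (host gene) which is propagated to the result.
#' @param sf Size factors named by library id, estimated from the gene-level
#'   matrix of the same libraries. Library sets must match exactly.
#' @param control,treatment Strain names to contrast.
#' @param spec [filter_spec()]; the same filtering procedure as for the
#'   coding genes.
#' @param lfc_threshold,alpha Passed to [classify_de()]; identical criteria
#'   and thresholds as the gene-level test.
#' @return A classified `data.frame` with additionally `gene_id` (when
#'   available) and `direction` (`more_retained` / `less_retained` /
#'   `NA` for non-significant), where direction follows the sign of the
#'   fold change of significant introns.
#' @export
dr_test <- function(intron_se, sf, control, treatment, spec = filter_spec(),
                    lfc_threshold = 1.5, alpha = 0.001) {
  if (is.null(names(sf)) ||
      !setequal(names(sf), colnames(intron_se)) ||
      length(sf) != ncol(intron_se))
    stop("size factors must cover exactly the libraries of the intron matrix")
  sf <- sf[colnames(intron_se)]
  res <- de_analysis(intron_se, control, treatment, spec = spec,
                     lfc_threshold = lfc_threshold, alpha = alpha, sf = sf)
  gid <- SummarizedExperiment::rowData(intron_se)$gene_id
  if (!is.null(gid))
    res$gene_id <- gid[match(res$feature_id, rownames(intron_se))]
  res$direction <- ifelse(
    res$status %in% c("up", "down"),
    ifelse(res$log2fc > 0, "more_retained", "less_retained"),
    NA_character_)
  res
}

#' Introns differentially retained in at least one mutant
#'
#' @param dr_list Named list of [dr_test()] results, one per mutant, over the
#'   same intron universe.
#' @return List with `introns` (ids significant in >= 1 mutant), `fc`, the
#'   introns-by-mutants matrix of estimated log2 fold changes (estimates are
#'   kept for non-significant cells), and `significant`, the matching logical
#'   matrix.
#' @export
union_dr <- function(dr_list) {
  stopifnot(length(dr_list) >= 1, !is.null(names(dr_list)))
  ids <- dr_list[[1L]]$feature_id
  for (d in dr_list)
    if (!setequal(d$feature_id, ids))
      stop("intron universes differ between comparisons")
  sig_any <- character(0)
  fc <- sig <- NULL
  for (m in names(dr_list)) {
    d <- dr_list[[m]]
    d <- d[match(ids, d$feature_id), ]
    s <- d$status %in% c("up", "down")
    sig_any <- union(sig_any, d$feature_id[s])
    fc <- cbind(fc, d$log2fc)
    sig <- cbind(sig, s)
  }
  dimnames(fc) <- dimnames(sig) <- list(ids, names(dr_list))
  introns <- ids[ids %in% sig_any]
  list(introns = introns,
       fc = fc[introns, , drop = FALSE],
       significant = sig[introns, , drop = FALSE])
}

#' Restrict DR introns to non-differentially-expressed host genes
#'
#' A retention change in an intron of a gene whose overall expression also
#' changed may simply track the host gene; restricting to hosts with status
#' `ns` in the same comparison isolates splicing-level effects. Host genes
#' removed by the gene-level low-count filter cannot be certified
#' non-differential, so their introns are excluded too.
#'
#' @param dr [dr_test()] result for one mutant.
#' @param gene_de [de_analysis()] result for the same mutant (must contain
#'   every host gene; an unknown host gene is a hard error).
#' @return The subset of `dr` rows that are significant and whose host gene
#'   status is `ns`.
#' @export
restrict_to_nonde <- function(dr, gene_de) {
  if (is.null(dr$gene_id)) stop("dr result lacks host gene ids")
  idx <- match(dr$gene_id, gene_de$feature_id)
  if (anyNA(idx))
    stop("host gene absent from the gene-level results: ",
         paste(unique(dr$gene_id[is.na(idx)]), collapse = ", "))
  sig <- dr$status %in% c("up", "down")
  keep <- sig & gene_de$status[idx] == "ns"
  dr[keep, , drop = FALSE]
}

#' Run differential retention against all mutants
#'
#' Estimates gene-derived size factors once (median-of-ratios on the
#' RPK-filtered gene matrix across all libraries, or total counts) and tests
#' every mutant against the control.
#'
#' @param intron_se,gene_se Intron and gene count containers over the same
#'   libraries.
#' @param control Control strain name.
#' @param mutants Mutant strain names; default all non-control strains.
#' @param spec,lfc_threshold,alpha As in [dr_test()].
#' @param normalization `"gene"` (borrow median-of-ratios factors from the
#'   complete gene dataset, the default) or `"total"` (total gene-level
#'   mapped counts).
#' @return Named list of [dr_test()] results, one per mutant, with the size
#'   factors used attached as attribute `sf`.
#' @export
dr_analysis <- function(intron_se, gene_se, control, mutants = NULL,
                        spec = filter_spec(), lfc_threshold = 1.5,
                        alpha = 0.001,
                        normalization = c("gene", "total")) {
  normalization <- match.arg(normalization)
  if (!setequal(colnames(intron_se), colnames(gene_se)))
    stop("intron and gene matrices cover different library sets")
  if (is.null(mutants))
    mutants <- setdiff(unique(strains_of(gene_se)), control)
  flt <- low_count_filter(gene_se, spec)
  gk <- counts_of(gene_se)[flt$kept, , drop = FALSE]
  sf <- if (normalization == "gene") size_factors(gk)
        else size_factors(gk, "total_count")
  out <- lapply(mutants, function(m)
    dr_test(intron_se, sf, control, m, spec = spec,
            lfc_threshold = lfc_threshold, alpha = alpha))
  names(out) <- mutants
  attr(out, "sf") <- sf
  out
}

#' Hierarchical clustering of the DR fold-change matrix
#'
#' Rows (introns) and columns (mutants) are clustered with Euclidean distance
#' and complete linkage, the display used for the retention heatmap.
#' Rows are pre-sorted by id so that the ordering is deterministic under
#' input permutation.
#'
#' @param fc Numeric matrix, introns x mutants, of log2 fold changes
#'   (non-significant cells keep their estimates; significance is a separate
#'   annotation).
#' @return List with `row_hclust`, `col_hclust` (`hclust` objects, `NULL`
#'   when that dimension has < 2 elements), and `row_order` / `col_order`
#'   (label vectors in dendrogram order).
#' @export
cluster_fold_changes <- function(fc) {
  fc <- as.matrix(fc)
  stopifnot(!is.null(rownames(fc)), !is.null(colnames(fc)), all(is.finite(fc)))
  fc <- fc[order(rownames(fc)), , drop = FALSE]
  row_h <- if (nrow(fc) >= 2)
    stats::hclust(stats::dist(fc, method = "euclidean"), method = "complete")
  col_h <- if (ncol(fc) >= 2)
    stats::hclust(stats::dist(t(fc), method = "euclidean"), method = "complete")
  list(row_hclust = row_h, col_hclust = col_h,
       row_order = if (is.null(row_h)) rownames(fc)
                   else rownames(fc)[row_h$order],
       col_order = if (is.null(col_h)) colnames(fc)
                   else colnames(fc)[col_h$order])
}

#' Correspondence-analysis clustering of libraries
#'
#' The count matrix is first discretized into five levels using the 20/40/
#' 60/80% quantiles of the nonzero entries as global breakpoints (zeros form
#' their own lowest level); correspondence analysis is then the SVD of the
#' standardized Pearson residuals of the discretized table, and libraries are
#' clustered on the Euclidean distances between their principal coordinates
#' over all retained axes, with average linkage.
#'
#' @param counts Count matrix or container, features x libraries.
#' @return List with `coords` (libraries x axes principal coordinates),
#'   `dist` (`dist` object), `hclust` (`NULL` for a single library),
#'   `discretized` (the level matrix), and `breaks` (the quantile
#'   breakpoints used).
#' @export
coa_library_clustering <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment")) counts <- counts_of(counts)
  m <- as.matrix(counts)
  nz <- m[m > 0]
  if (length(nz) == 0) stop("count matrix is all zero")
  breaks <- stats::quantile(nz, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  disc <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  disc[m > 0] <- 1L + findInterval(m[m > 0], breaks, left.open = TRUE)
  if (ncol(m) == 1L)
    return(list(coords = matrix(0, 1, 1, dimnames = list(colnames(m), "CA1")),
                dist = stats::dist(matrix(0, 1, 1)), hclust = NULL,
                discretized = disc, breaks = breaks))
  use <- rowSums(disc) > 0
  N <- disc[use, , drop = FALSE]
  P <- N / sum(N)
  r <- rowSums(P)
  cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  keep <- sv$d > 1e-12
  if (!any(keep)) {
    # no structure at all (e.g. identical columns): one zero axis
    coords <- matrix(0, ncol(m), 1L)
  } else {
    d <- sv$d[keep]
    V <- sv$v[, keep, drop = FALSE]
    coords <- sweep(V, 1L, sqrt(cc), "/") %*% diag(d, nrow = length(d))
  }
  rownames(coords) <- colnames(m)
  colnames(coords) <- paste0("CA", seq_len(ncol(coords)))
  dd <- stats::dist(coords)
  hc <- if (ncol(m) >= 2) stats::hclust(dd, method = "average")
  list(coords = coords, dist = dd, hclust = hc, discretized = disc,
       breaks = breaks)
}
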