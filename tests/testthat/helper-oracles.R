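# Independent oracles and small random-instance generators used across the
# suite. Each oracle is a direct, naive transcription of the definition it
# checks, kept free of the package's own code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# Per-base intersection-strict assignment: for every aligned base collect the
# set of covering features, intersect the sets, classify by the size of the
# intersection.
naive_assign <- function(reads, features) {
  fid <- features$feature_id
  fchr <- as.character(GenomicRanges::seqnames(features))
  fs <- GenomicRanges::start(features)
  fe <- GenomicRanges::end(features)
  vapply(seq_along(reads), function(i) {
    b <- reads[[i]]
    chr <- as.character(GenomicRanges::seqnames(b))
    bs <- GenomicRanges::start(b)
    be <- GenomicRanges::end(b)
    sets <- list()
    for (j in seq_along(b)) {
      for (p in seq(bs[j], be[j])) {
        sets[[length(sets) + 1L]] <-
          unique(fid[fchr == chr[j] & fs <= p & fe >= p])
      }
    }
    common <- Reduce(intersect, sets)
    if (length(common) == 0L) "NO_FEATURE"
    else if (length(common) == 1L) common
    else "AMBIGUOUS"
  }, character(1L))
}

# Random counting instance: overlapping features on two chromosomes, a mix of
# single-block and gapped reads, some intergenic, some off-chromosome.
random_counting_instance <- function(seed, n_features = 50L, n_reads = 500L,
                                     genome = 10000L) {
  set.seed(seed)
  fchr <- sample(c("c1", "c2"), n_features, replace = TRUE)
  fs <- sample.int(genome - 500L, n_features, replace = TRUE)
  fw <- sample(30:400, n_features, replace = TRUE)
  features <- GenomicRanges::GRanges(fchr, IRanges::IRanges(fs, width = fw))
  features$feature_id <- sprintf("f%03d", seq_len(n_features))

  two_block <- stats::runif(n_reads) < 0.3
  rchr <- sample(c("c1", "c2", "c3"), n_reads, replace = TRUE,
                 prob = c(0.48, 0.48, 0.04))
  r1s <- sample.int(genome, n_reads, replace = TRUE)
  r1w <- sample(10:60, n_reads, replace = TRUE)
  gap <- sample(20:200, n_reads, replace = TRUE)
  r2w <- sample(10:60, n_reads, replace = TRUE)
  starts <- c(r1s, (r1s + r1w + gap)[two_block])
  widths <- c(r1w, r2w[two_block])
  chrs <- c(rchr, rchr[two_block])
  rid <- c(seq_len(n_reads), seq_len(n_reads)[two_block])
  gr <- GenomicRanges::GRanges(chrs, IRanges::IRanges(starts, width = widths))
  reads <- S4Vectors::split(gr, factor(rid, levels = seq_len(n_reads)))
  names(reads) <- sprintf("r%04d", seq_len(n_reads))
  list(reads = reads, features = features)
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, m * p[o] / seq_len(m))
  adj <- vapply(seq_len(m), function(i) min(q[i:m]), numeric(1L))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive small-parsimony oracles: enumerate every labeling of the
# internal nodes. dollo = TRUE restricts to present-at-root, losses-only
# labelings and counts loss edges; otherwise counts all state changes.
enum_parsimony <- function(tree, presence, dollo = FALSE) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  internals <- seq.int(n_tip + 1L, n_node)
  states <- integer(n_node)
  states[seq_len(n_tip)] <- as.integer(presence[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^length(internals) - 1L)) {
    states[internals] <- bitwAnd(bitwShiftR(mask, seq_along(internals) - 1L), 1L)
    parent <- states[tree$edge[, 1L]]
    child <- states[tree$edge[, 2L]]
    if (dollo) {
      if (states[n_tip + 1L] != 1L) next        # single origin at the root
      if (any(parent == 0L & child == 1L)) next # losses only
      best <- min(best, sum(parent == 1L & child == 0L))
    } else {
      best <- min(best, sum(parent != child))
    }
  }
  best
}

random_presence <- function(tree, seed) {
  set.seed(seed)
  repeat {
    pres <- stats::setNames(stats::runif(length(tree$tip.label)) < 0.5,
                            tree$tip.label)
    if (any(pres)) return(pres)  # the Dollo model needs >= 1 present tip
  }
}

counts_of_se <- function(se) SummarizedExperiment::assay(se, "counts")

# Small deterministic count container used by several tests.
toy_se <- function(counts, lengths = NULL, strains = NULL) {
  if (is.null(lengths)) lengths <- rep(1000L, nrow(counts))
  meta <- NULL
  if (!is.null(strains))
    meta <- data.frame(library_id = colnames(counts), strain = strains,
                       replicate = stats::ave(seq_along(strains), strains,
                                              FUN = seq_along))
  count_matrix(counts, lengths = lengths, meta = meta)
}

# GFF3 text fixture writer.
write_gff3 <- function(lines, file = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), file)
  file
}
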