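#' Read aligned reads from a SAM or BAM file
#'
#' Primary alignments only: secondary, supplementary, and unmapped records are
#' skipped. Gapped alignments (N/D cigar operations) yield multiple aligned
#' blocks per read.
#'
#' @param file Path to a SAM (converted on the fly) or BAM file.
#' @return A [GenomicRanges::GRangesList]: one element per read (named by read
#'   id) holding its aligned blocks in reference coordinates.
#' @export
read_alignments <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "qname")
  aln <- GenomicAlignments::readGAlignments(file, param = param)
  blocks <- GenomicAlignments::grglist(aln)
  names(blocks) <- S4Vectors::mcols(aln)$qname
  blocks
}

#' Assign reads to features with intersection-strict semantics
#'
#' For every aligned base of a read, take the set of features covering that
#' base, then intersect these sets over all bases of all blocks. A singleton
#' intersection assigns the read to that feature; an empty intersection (any
#' uncovered base, or no common feature) yields `"NO_FEATURE"`; a larger
#' intersection yields `"AMBIGUOUS"`. Equivalently, a read is assigned to a
#' feature iff that feature contains every aligned block, which is how the
#' assignment is computed.
#'
#' @param reads `GRangesList` of aligned blocks per read (see
#'   [read_alignments()]); single-block reads may also be given as a plain
#'   `GRanges`.
#' @param features `GRanges` with a `feature_id` metadata column. Features on
#'   chromosomes absent from a read's chromosome simply never cover it.
#' @param stranded If `FALSE` (default, matching non-strand-specific library
#'   preparation) feature strand is ignored.
#' @return Character vector, one entry per read: a feature id, `"AMBIGUOUS"`,
#'   or `"NO_FEATURE"`. Named by read names when present.
#' @export
assign_reads <- function(reads, features, stranded = FALSE) {
  if (methods::is(reads, "GRanges")) reads <- methods::as(reads, "GRangesList")
  stopifnot(methods::is(reads, "GRangesList"),
            methods::is(features, "GRanges"),
            !is.null(features$feature_id))
  # a feature may span several intervals (rows sharing a feature_id);
  # a base is covered by the feature when any of its intervals covers it
  rf <- GenomicRanges::reduce(
    S4Vectors::split(features, features$feature_id),
    ignore.strand = !stranded)
  ru <- unlist(rf, use.names = TRUE)
  fid <- names(ru)
  nb <- lengths(reads)
  u <- unlist(reads, use.names = FALSE)
  ridx <- rep(seq_along(reads), nb)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(
    u, ru, type = "within", ignore.strand = !stranded))
  out <- rep("NO_FEATURE", length(reads))
  if (length(ov)) {
    # reduced intervals of one feature are disjoint, so a block lies within
    # the feature's union iff it lies within exactly one reduced interval
    dt <- data.table::data.table(read = ridx[S4Vectors::queryHits(ov)],
                                 feat = fid[S4Vectors::subjectHits(ov)])
    full <- dt[, list(nb_hit = .N), by = c("read", "feat")]
    full <- full[full$nb_hit == nb[full$read], ]
    hits <- full[, list(n_feat = .N, feat1 = feat[1L]), by = "read"]
    out[hits$read[hits$n_feat > 1L]] <- "AMBIGUOUS"
    one <- hits[hits$n_feat == 1L, ]
    out[one$read] <- one$feat1
  }
  names(out) <- names(reads)
  out
}

#' Count reads per feature across libraries
#'
#' Runs intersection-strict assignment library by library and tabulates
#' assigned reads into an integer feature-by-library matrix. Gene and intron
#' counting are meant to be run as two separate passes over their own feature
#' sets; a combined set would turn every exon/intron boundary read ambiguous.
#'
#' @param alignments Named list, one element per library: a `GRangesList` (or
#'   `GRanges`) of reads, or a path to a SAM/BAM file. Names are library ids.
#' @param features `GRanges` with `feature_id` metadata.
#' @param meta Optional `data.frame` with columns `library_id`, `strain`,
#'   `replicate`. Every library in `alignments` must appear; an unknown
#'   library is a hard error.
#' @param stranded Passed to [assign_reads()].
#' @return List with `se`, a [SummarizedExperiment::SummarizedExperiment]
#'   (assay `counts`, rowData `length`, colData from `meta`), and `tally`,
#'   a per-library `data.frame` of `assigned`, `ambiguous` and `no_feature`
#'   read counts (their sum is the number of reads processed).
#' @export
count_reads <- function(alignments, features, meta = NULL, stranded = FALSE) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  libs <- names(alignments)
  if (!is.null(meta)) {
    missing <- setdiff(libs, meta$library_id)
    if (length(missing))
      stop("library not in sample sheet: ", paste(missing, collapse = ", "))
    meta <- meta[match(libs, meta$library_id), , drop = FALSE]
  }
  fid <- unique(features$feature_id)
  # feature length = bp covered by the feature's (possibly several) intervals
  flen <- sum(GenomicRanges::width(GenomicRanges::reduce(
    S4Vectors::split(features, factor(features$feature_id, levels = fid)),
    ignore.strand = TRUE)))
  counts <- matrix(0L, nrow = length(fid), ncol = length(libs),
                   dimnames = list(fid, libs))
  tally <- data.frame(library_id = libs, assigned = 0L, ambiguous = 0L,
                      no_feature = 0L, row.names = libs)
  for (lib in libs) {
    reads <- alignments[[lib]]
    if (is.character(reads)) reads <- read_alignments(reads)
    a <- assign_reads(reads, features, stranded = stranded)
    tally[lib, "ambiguous"] <- sum(a == "AMBIGUOUS")
    tally[lib, "no_feature"] <- sum(a == "NO_FEATURE")
    assigned <- a[!(a %in% c("AMBIGUOUS", "NO_FEATURE"))]
    tally[lib, "assigned"] <- length(assigned)
    tab <- table(factor(assigned, levels = fid))
    counts[, lib] <- as.integer(tab)
  }
  se <- count_matrix(counts, lengths = flen, meta = meta)
  list(se = se, tally = tally)
}

#' Build a count-matrix container
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   libraries in columns (colnames = library ids).
#' @param lengths Feature lengths in bp, recycled against rows.
#' @param meta Optional library metadata `data.frame` (columns `library_id`,
#'   `strain`, `replicate`).
#' @return A `SummarizedExperiment` with assay `counts`.
#' @export
count_matrix <- function(counts, lengths, meta = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 0L || !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(counts >= 0), all(counts == round(counts)),
            all(lengths > 0))
  mode(counts) <- "integer"
  cd <- if (is.null(meta)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    S4Vectors::DataFrame(meta[match(colnames(counts), meta$library_id), ,
                               drop = FALSE],
                         row.names = colnames(counts))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = rep(as.integer(lengths),
                                                length.out = nrow(counts)),
                                   row.names = rownames(counts)),
    colData = cd)
}

counts_of <- function(se) SummarizedExperiment::assay(se, "counts")
lengths_of <- function(se) SummarizedExperiment::rowData(se)$length
strains_of <- function(se) SummarizedExperiment::colData(se)$strain

#' Reads per kilobase of feature length
#'
#' `RPK = count * 1000 / length_bp`, computed from raw counts with no depth
#' normalization: the low-expression filter this feeds precedes any
#' normalization step.
#'
#' @param se A `SummarizedExperiment` from [count_matrix()], or an integer
#'   matrix if `lengths` is supplied.
#' @param lengths Feature lengths in bp when `se` is a bare matrix.
#' @return Numeric matrix of RPK values with the dimensions of the counts.
#' @export
rpk <- function(se, lengths = NULL) {
  if (methods::is(se, "SummarizedExperiment")) {
    m <- counts_of(se)
    lengths <- lengths_of(se)
  } else {
    m <- as.matrix(se)
  }
  if (is.null(lengths) || any(lengths <= 0)) stop("feature lengths must be > 0")
  m * 1000 / lengths
}

#' Write a count matrix as TSV
#'
#' Columns: `feature_id`, `length`, then one column per library.
#'
#' @param se `SummarizedExperiment` from [count_matrix()].
#' @param file Output path.
#' @param comment Optional character vector written as leading `#` lines.
#' @return `file`, invisibly.
#' @export
write_count_matrix <- function(se, file, comment = NULL) {
  df <- data.frame(feature_id = rownames(se), length = lengths_of(se),
                   counts_of(se), check.names = FALSE)
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param file TSV path.
#' @param meta Optional library metadata (see [count_matrix()]).
#' @return A `SummarizedExperiment`.
#' @export
read_count_matrix <- function(file, meta = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$feature_id
  count_matrix(counts, lengths = df$length, meta = meta)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `library_id`, `strain`, `replicate` (extra columns such
#' as alignment paths are carried through).
#'
#' @param file TSV path.
#' @return A `data.frame`.
#' @export
read_sample_sheet <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("library_id", "strain", "replicate")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$library_id)) stop("duplicated library_id in sample sheet")
  df
}
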