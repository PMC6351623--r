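#' Parse a GFF3 gene annotation into per-gene exon models
#'
#' Reads a GFF3 file with a gene/mRNA/exon (or CDS) hierarchy and returns one
#' exon model per coding gene. When a gene carries several transcripts the
#' union of their exons is used (with a warning), since intron derivation below
#' works on the gaps of the per-gene exon union.
#'
#' @param file Path to a GFF3 file.
#' @return A named [GenomicRanges::GRangesList] of exon ranges, one element per
#'   gene, exons sorted by coordinate. Gene ids are taken from the `ID`
#'   attribute of `gene` features.
#' @details Coordinates follow the GFF3 and GenomicRanges convention: 1-based,
#'   closed intervals. Exons overlapping within a single transcript are a hard
#'   error, as is an exon whose `Parent` resolves to no known transcript or
#'   gene.
#' @export
parse_annotation <- function(file) {
  gff <- rtracklayer::import(file, format = "gff3")
  type <- as.character(gff$type)

  genes <- gff[type == "gene"]
  if (length(genes) == 0L) stop("annotation contains no 'gene' features")
  gene_ids <- as.character(genes$ID)
  if (anyNA(gene_ids) || any(gene_ids == ""))
    stop("every gene feature needs an ID attribute")
  if (anyDuplicated(gene_ids)) stop("duplicated gene IDs in annotation")

  tx <- gff[type %in% c("mRNA", "transcript")]
  tx2gene <- character(0)
  if (length(tx)) {
    tx_parent <- .first_parent(tx$Parent, as.character(tx$ID))
    tx2gene <- stats::setNames(tx_parent, as.character(tx$ID))
    bad <- !(tx2gene %in% gene_ids)
    if (any(bad))
      stop("transcript ", names(tx2gene)[bad][1L], " references unknown gene ",
           tx2gene[bad][1L])
  }

  ex <- gff[type == "exon"]
  if (length(ex) == 0L) ex <- gff[type == "CDS"]
  if (length(ex) == 0L) stop("annotation contains no exon or CDS features")
  ex_parent <- .first_parent(ex$Parent, feature_label(ex))

  # resolve each exon's parent to a gene id, via its transcript if necessary
  ex_gene <- ifelse(ex_parent %in% names(tx2gene),
                    tx2gene[ex_parent],
                    ex_parent)
  unknown <- !(ex_gene %in% gene_ids)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop("exon at ", feature_label(ex)[i], " references unknown parent '",
         ex_parent[i], "'")
  }

  # overlapping exons within one transcript are malformed input
  by_tx <- S4Vectors::split(ex, ex_parent)
  shrunk <- sum(lengths(GenomicRanges::reduce(by_tx))) < lengths(by_tx)
  if (any(shrunk))
    stop("overlapping exons within transcript '", names(by_tx)[shrunk][1L], "'")

  multi_tx <- table(unname(tx2gene))
  if (any(multi_tx > 1L))
    warning(sum(multi_tx > 1L), " gene(s) with multiple transcripts; ",
            "using the union of exons per gene")

  models <- GenomicRanges::reduce(
    S4Vectors::split(ex, factor(ex_gene, levels = gene_ids)))
  one_chrom <- vapply(models, function(g)
    length(unique(as.character(GenomicRanges::seqnames(g)))) == 1L, TRUE)
  if (!all(one_chrom))
    stop("gene '", names(models)[!one_chrom][1L], "' has exons on >1 chromosome")
  models <- GenomicRanges::sort(models, ignore.strand = TRUE)
  models
}

.first_parent <- function(parent, labels) {
  n <- lengths(parent)
  if (any(n == 0L))
    stop("feature ", labels[which(n == 0L)[1L]], " has no Parent attribute")
  vapply(parent, `[[`, character(1L), 1L)
}

feature_label <- function(gr) {
  paste0(GenomicRanges::seqnames(gr), ":", GenomicRanges::start(gr), "-",
         GenomicRanges::end(gr))
}

#' Gene lengths (sum of exon widths)
#'
#' @param genes A `GRangesList` of exon models, as returned by
#'   [parse_annotation()].
#' @return Named integer vector of summed exon lengths in bp.
#' @export
gene_lengths <- function(genes) {
  stats::setNames(sum(GenomicRanges::width(genes)), names(genes))
}

#' Derive intron features from gene exon models
#'
#' Introns are the gaps between consecutive exons of a gene. Gaps shorter than
#' `min_intron_length` are dropped silently (the number dropped is reported as
#' a message). Introns are numbered in transcription order, i.e. 1 is the
#' most 5' intron, which on the minus strand is the one with the highest
#' coordinates.
#'
#' @param genes `GRangesList` of exon models.
#' @param min_intron_length Minimum gap length in bp to keep, inclusive:
#'   the default 50 keeps a 50 bp gap.
#' @return A [GenomicRanges::GRanges] of introns with metadata columns
#'   `intron_id` (gene id plus ordinal, e.g. `g1_i2`) and `gene_id`.
#' @export
extract_introns <- function(genes, min_intron_length = 50) {
  stopifnot(min_intron_length >= 1)
  spans <- unlist(range(genes, ignore.strand = TRUE))
  gaps <- IRanges::psetdiff(spans, genes, ignore.strand = TRUE)
  gr <- unlist(gaps, use.names = FALSE)
  if (length(gr) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$intron_id <- character(0)
    gr$gene_id <- character(0)
    return(gr)
  }
  gene_id <- rep(names(gaps), lengths(gaps))
  sr <- S4Vectors::runValue(GenomicRanges::strand(genes))
  if (any(lengths(sr) != 1L))
    stop("gene '", names(genes)[lengths(sr) != 1L][1L], "' mixes strands")
  strand_by_gene <- stats::setNames(as.character(unlist(sr)), names(genes))
  strand <- unname(strand_by_gene[gene_id])

  keep <- GenomicRanges::width(gr) >= min_intron_length
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " gap(s) below ", min_intron_length, " bp dropped")
  gr <- gr[keep]
  gene_id <- gene_id[keep]
  strand <- strand[keep]
  if (length(gr) == 0L) {
    gr$intron_id <- character(0)
    gr$gene_id <- character(0)
    return(gr)
  }

  # transcription-order ordinal: ascending start on +, descending on -
  ord <- ifelse(strand == "-", -GenomicRanges::start(gr), GenomicRanges::start(gr))
  idx <- stats::ave(ord, gene_id, FUN = rank)
  GenomicRanges::strand(gr) <- strand
  gr$intron_id <- paste0(gene_id, "_i", as.integer(idx))
  gr$gene_id <- gene_id
  stopifnot(!anyDuplicated(gr$intron_id))
  gr
}

#' Write the dedicated intron-only GFF3 file
#'
#' Emits one `intron` feature line per intron, carrying `ID` (intron id) and
#' `Parent` (host gene id) attributes. Writing then reading with
#' [read_intron_gff()] reproduces coordinates and ids exactly.
#'
#' @param introns `GRanges` from [extract_introns()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_intron_gff <- function(introns, file) {
  gr <- GenomicRanges::granges(introns)
  n <- length(gr)
  if (n == 0L) {  # header-only file
    writeLines("##gff-version 3", file)
    return(invisible(file))
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = rep("intronr", n),
    type = rep("intron", n),
    ID = introns$intron_id,
    Parent = introns$gene_id)
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Read an intron-only GFF3 file
#'
#' @param file Path written by [write_intron_gff()] (or any GFF3 whose
#'   `intron` features carry `ID` and `Parent`).
#' @return `GRanges` with `intron_id` and `gene_id` metadata columns.
#' @export
read_intron_gff <- function(file) {
  gff <- rtracklayer::import(file, format = "gff3")
  gff <- gff[as.character(gff$type) == "intron"]
  out <- GenomicRanges::granges(gff)
  out$intron_id <- as.character(gff$ID)
  out$gene_id <- vapply(gff$Parent, `[[`, character(1L), 1L)
  out
}

#' Feature set of whole gene loci
#'
#' The gene-level counting pass uses the complete locus span of each gene
#' (first to last exon, introns included) as its feature interval.
#'
#' @param genes `GRangesList` of exon models.
#' @return `GRanges` with a `feature_id` metadata column.
#' @export
gene_loci <- function(genes) {
  loci <- unlist(range(genes, ignore.strand = TRUE))
  loci$feature_id <- names(loci)
  names(loci) <- NULL
  loci
}

#' Intron features formatted for counting
#'
#' @param introns `GRanges` from [extract_introns()].
#' @return `GRanges` with a `feature_id` column set to the intron ids.
#' @export
intron_features <- function(introns) {
  out <- GenomicRanges::granges(introns)
  out$feature_id <- introns$intron_id
  out
}
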