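#' Describe one strain of a simulation scenario
#'
#' @param name Strain name.
#' @param de_fraction Fraction of genes truly differentially expressed in
#'   this strain.
#' @param de_log2fc_mean,de_log2fc_sd Magnitude distribution of true gene
#'   effects (sign drawn at random).
#' @param dr_fraction Fraction of introns truly differentially retained.
#' @param dr_multiplier Retention multiplier for true DR introns (applied as
#'   is for `dr_direction = "more"`, inverted for `"less"`).
#' @param dr_direction `"more"` or `"less"` retained relative to control.
#' @param global_retention_multiplier Multiplier applied to the retention of
#'   every intron of the strain (models a global shift of intron mass that
#'   leaves gene-level depth untouched; default 1 = none).
#' @return A list describing the strain.
#' @export
strain_spec <- function(name, de_fraction = 0, de_log2fc_mean = 2.5,
                        de_log2fc_sd = 0.5, dr_fraction = 0,
                        dr_multiplier = 8, dr_direction = c("more", "less"),
                        global_retention_multiplier = 1) {
  dr_direction <- match.arg(dr_direction)
  stopifnot(de_fraction >= 0, de_fraction <= 1,
            dr_fraction >= 0, dr_fraction <= 1,
            dr_multiplier > 0, global_retention_multiplier > 0)
  list(name = name, de_fraction = de_fraction,
       de_log2fc_mean = de_log2fc_mean, de_log2fc_sd = de_log2fc_sd,
       dr_fraction = dr_fraction, dr_multiplier = dr_multiplier,
       dr_direction = dr_direction,
       global_retention_multiplier = global_retention_multiplier)
}

#' Simulation scenario for the five-strain, three-replicate design
#'
#' The defaults emulate the structure of the study design the analysis is
#' built for: one control strain and four mutants, three biological
#' replicates each (15 libraries), library depths spread by a factor of about
#' 1.6 (mirroring the 18-30 million read spread of real libraries, scaled
#' down to tens of thousands of reads so that a full run takes seconds),
#' log-normal baseline gene expression, negative-binomial noise, and intron
#' retention as a fraction of host-gene expression. An NMD-mutant-like strain
#' shows a broad retention increase; an EJC-mutant-like strain a broad
#' decrease plus many gene-level effects; the remaining two mutants have
#' small effect sets.
#'
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @param n_genes Number of genes.
#' @param intron_probability Probability that a gene carries one intron.
#' @param intron_length_range,exon_length_range Uniform bp ranges.
#' @param depth_factor_range Range of per-library relative depth multipliers.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   per-gene expected counts.
#' @param host_meanlog_boost,host_sdlog Intron-bearing genes draw their
#'   baseline from `lognormal(baseline_meanlog + host_meanlog_boost,
#'   host_sdlog)` instead: in yeasts the intron-containing genes skew
#'   strongly toward highly (and uniformly) expressed genes, and the boost
#'   keeps intron coverage in the regime the retention test is designed for.
#' @param dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha mu^2).
#' @param rho_range Range of baseline intron retention fractions (intron
#'   mean read density as a fraction of host-gene mean).
#' @param n_replicates Replicates per strain.
#' @param strains List of [strain_spec()]s; the first is the control.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(seed = 20260929L,
                                n_genes = 500L,
                                intron_probability = 0.3,
                                intron_length_range = c(50L, 400L),
                                exon_length_range = c(200L, 800L),
                                depth_factor_range = c(1, 1.6),
                                baseline_meanlog = log(40),
                                baseline_sdlog = 1,
                                host_meanlog_boost = 1.8,
                                host_sdlog = 0.5,
                                dispersion = 0.05,
                                rho_range = c(0.05, 0.2),
                                n_replicates = 3L,
                                strains = NULL) {
  if (is.null(strains))
    strains <- list(
      strain_spec("ku70"),
      strain_spec("upf1", de_fraction = 0.05, dr_fraction = 0.25,
                  dr_direction = "more"),
      strain_spec("upf2", de_fraction = 0.02, dr_fraction = 0.10,
                  dr_direction = "more"),
      strain_spec("mago", de_fraction = 0.02, dr_fraction = 0.04,
                  dr_direction = "more"),
      strain_spec("y14", de_fraction = 0.15, dr_fraction = 0.30,
                  dr_direction = "less"))
  stopifnot(seed == as.integer(seed), n_genes >= 1,
            intron_probability >= 0, intron_probability <= 1,
            dispersion > 0, all(rho_range > 0), all(rho_range < 1),
            n_replicates >= 2, length(strains) >= 2)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 intron_probability = intron_probability,
                 intron_length_range = intron_length_range,
                 exon_length_range = exon_length_range,
                 depth_factor_range = depth_factor_range,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 host_meanlog_boost = host_meanlog_boost,
                 host_sdlog = host_sdlog,
                 dispersion = dispersion, rho_range = rho_range,
                 n_replicates = as.integer(n_replicates), strains = strains),
            class = "simulation_scenario")
}

#' Simulate a gene annotation
#'
#' Genes are laid out without overlap on synthetic chromosomes (about 1 Mb
#' each, 200 bp intergenic gaps). A gene carries either a single exon or two
#' exons separated by one intron of at least the minimum selectable length.
#' Fully reproducible from the scenario seed.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `genes` (exon `GRangesList`), `introns` (`GRanges` as
#'   from [extract_introns()]) and `seqlengths` (named chromosome lengths).
#' @export
simulate_annotation <- function(scenario) {
  set.seed(scenario$seed + 1L)
  n <- scenario$n_genes
  has_intron <- stats::runif(n) < scenario$intron_probability
  e1 <- sample(scenario$exon_length_range[1]:scenario$exon_length_range[2],
               n, replace = TRUE)
  e2 <- sample(scenario$exon_length_range[1]:scenario$exon_length_range[2],
               n, replace = TRUE)
  il <- sample(scenario$intron_length_range[1]:scenario$intron_length_range[2],
               n, replace = TRUE)
  span <- ifelse(has_intron, e1 + il + e2, e1)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  gap <- 200L
  chrom_cap <- 1e6
  start <- integer(n); chrom <- integer(n)
  pos <- 1L; ch <- 1L
  for (i in seq_len(n)) {
    if (pos + span[i] > chrom_cap) { ch <- ch + 1L; pos <- 1L }
    start[i] <- pos; chrom[i] <- ch
    pos <- pos + span[i] + gap
  }
  gene_id <- sprintf("g%04d", seq_len(n))
  chrom_name <- paste0("chrS", chrom)

  ex_start <- ex_end <- ex_gene <- ex_chr <- ex_strand <- list()
  for (i in seq_len(n)) {
    if (has_intron[i]) {
      s <- c(start[i], start[i] + e1[i] + il[i])
      e <- c(start[i] + e1[i] - 1L, start[i] + e1[i] + il[i] + e2[i] - 1L)
    } else {
      s <- start[i]; e <- start[i] + e1[i] - 1L
    }
    ex_start[[i]] <- s; ex_end[[i]] <- e
    ex_gene[[i]] <- rep(gene_id[i], length(s))
    ex_chr[[i]] <- rep(chrom_name[i], length(s))
    ex_strand[[i]] <- rep(strand[i], length(s))
  }
  exons <- GenomicRanges::GRanges(
    unlist(ex_chr),
    IRanges::IRanges(unlist(ex_start), unlist(ex_end)),
    strand = unlist(ex_strand))
  genes <- S4Vectors::split(exons, factor(unlist(ex_gene), levels = gene_id))
  introns <- suppressMessages(
    extract_introns(genes,
                    min_intron_length = scenario$intron_length_range[1]))
  seqlens <- tapply(start + span, chrom_name, max) + gap
  list(genes = genes, introns = introns,
       seqlengths = seqlens[unique(chrom_name)])
}

#' Simulate gene and intron count matrices with ground truth
#'
#' Gene counts are `NB(mean = depth_j * mu_g * 2^beta, dispersion alpha)`
#' where `beta` is the strain's true gene effect (0 for unaffected genes);
#' intron counts are `NB(mean = depth_j * mu_g * rho_i * m, alpha)` where
#' `rho_i` is the baseline retention fraction and `m` the strain's retention
#' multiplier for that intron (including any global retention shift). The
#' control strain has all multipliers at 1.
#'
#' @param scenario A [simulation_scenario()].
#' @param annotation Output of [simulate_annotation()].
#' @return List with `gene_se`, `intron_se` (count containers with library
#'   metadata) and `truth`: per-strain data frames of true DE genes
#'   (`gene_id`, `log2fc`) and true DR introns (`intron_id`, `direction`,
#'   `multiplier`), plus `depth_factors`, `mu`, `rho`.
#' @export
simulate_counts <- function(scenario, annotation) {
  set.seed(scenario$seed + 2L)
  genes <- annotation$genes
  introns <- annotation$introns
  gene_id <- names(genes)
  intron_id <- introns$intron_id
  n_g <- length(gene_id); n_i <- length(intron_id)
  reps <- scenario$n_replicates
  strains <- scenario$strains
  strain_names <- vapply(strains, `[[`, "", "name")

  mu <- stats::rlnorm(n_g, scenario$baseline_meanlog, scenario$baseline_sdlog)
  names(mu) <- gene_id
  hosts <- unique(introns$gene_id)
  if (length(hosts))
    mu[hosts] <- stats::rlnorm(
      length(hosts),
      scenario$baseline_meanlog + scenario$host_meanlog_boost,
      scenario$host_sdlog)
  rho <- stats::runif(n_i, scenario$rho_range[1], scenario$rho_range[2])
  names(rho) <- intron_id
  host <- introns$gene_id

  lib_id <- as.vector(vapply(strain_names,
                             function(s) paste0(s, "_r", seq_len(reps)),
                             character(reps)))
  lib_strain <- rep(strain_names, each = reps)
  depth <- stats::runif(length(lib_id), scenario$depth_factor_range[1],
                        scenario$depth_factor_range[2])
  names(depth) <- lib_id

  beta <- matrix(0, n_g, length(strains),
                 dimnames = list(gene_id, strain_names))
  imult <- matrix(1, n_i, length(strains),
                  dimnames = list(intron_id, strain_names))
  truth_de <- list(); truth_dr <- list()
  for (k in seq_along(strains)[-1L]) {
    st <- strains[[k]]
    nde <- round(st$de_fraction * n_g)
    if (nde > 0) {
      idx <- sample(n_g, nde)
      eff <- sample(c(-1, 1), nde, replace = TRUE) *
        abs(stats::rnorm(nde, st$de_log2fc_mean, st$de_log2fc_sd))
      beta[idx, k] <- eff
      truth_de[[st$name]] <- data.frame(gene_id = gene_id[idx], log2fc = eff,
                                        stringsAsFactors = FALSE)
    } else truth_de[[st$name]] <- data.frame(gene_id = character(0),
                                             log2fc = numeric(0))
    ndr <- round(st$dr_fraction * n_i)
    if (ndr > 0) {
      idx <- sample(n_i, ndr)
      m <- if (st$dr_direction == "more") st$dr_multiplier
           else 1 / st$dr_multiplier
      imult[idx, k] <- m
      truth_dr[[st$name]] <- data.frame(
        intron_id = intron_id[idx],
        direction = ifelse(m > 1, "more_retained", "less_retained"),
        multiplier = m, stringsAsFactors = FALSE)
    } else truth_dr[[st$name]] <- data.frame(intron_id = character(0),
                                             direction = character(0),
                                             multiplier = numeric(0))
    imult[, k] <- imult[, k] * st$global_retention_multiplier
  }

  size <- 1 / scenario$dispersion
  gene_counts <- matrix(0L, n_g, length(lib_id),
                        dimnames = list(gene_id, lib_id))
  intron_counts <- matrix(0L, n_i, length(lib_id),
                          dimnames = list(intron_id, lib_id))
  for (j in seq_along(lib_id)) {
    s <- lib_strain[j]
    gmean <- depth[j] * mu * 2^beta[, s]
    gene_counts[, j] <- stats::rnbinom(n_g, mu = gmean, size = size)
    if (n_i > 0) {
      im <- depth[j] * mu[host] * rho * imult[, s]
      intron_counts[, j] <- stats::rnbinom(n_i, mu = im, size = size)
    }
  }
  meta <- data.frame(library_id = lib_id, strain = lib_strain,
                     replicate = rep(seq_len(reps), length(strains)),
                     stringsAsFactors = FALSE)
  gene_se <- count_matrix(gene_counts, lengths = gene_lengths(genes)[gene_id],
                          meta = meta)
  intron_se <- count_matrix(intron_counts,
                            lengths = GenomicRanges::width(introns),
                            meta = meta)
  SummarizedExperiment::rowData(intron_se)$gene_id <- host
  list(gene_se = gene_se, intron_se = intron_se,
       truth = list(de_genes = truth_de, dr_introns = truth_dr,
                    depth_factors = depth / exp(mean(log(depth))),
                    mu = mu, rho = rho))
}

#' Simulate an aligned-read stream matching a count matrix
#'
#' Emits, for every counted unit, one single-block read placed uniformly
#' inside its feature, so that intersection-strict counting against the same
#' feature set reproduces the matrix exactly. A nonzero `boundary_fraction`
#' instead places that fraction of reads straddling the feature's start
#' boundary, which makes them ambiguous in a combined gene-plus-intron
#' feature set (used to exercise the counting contract, not for count-level
#' truth).
#'
#' @param se Count container whose rownames match `features$feature_id`.
#' @param features `GRanges` with `feature_id`.
#' @param read_length Read length in bp (capped at the feature length).
#' @param boundary_fraction Fraction of reads straddling feature starts.
#' @param seed Integer seed.
#' @return Named list (one per library) of `GRanges`, each range one
#'   single-block read, names carrying read ids.
#' @export
simulate_reads <- function(se, features, read_length = 30L,
                           boundary_fraction = 0, seed = 1L) {
  stopifnot(all(rownames(se) %in% features$feature_id))
  set.seed(seed)
  f <- features[match(rownames(se), features$feature_id)]
  counts <- counts_of(se)
  out <- vector("list", ncol(counts))
  names(out) <- colnames(counts)
  for (j in seq_len(ncol(counts))) {
    k <- counts[, j]
    idx <- rep(seq_along(k), k)
    if (length(idx) == 0L) {
      out[[j]] <- GenomicRanges::GRanges()
      next
    }
    fs <- GenomicRanges::start(f)[idx]
    fe <- GenomicRanges::end(f)[idx]
    len <- pmin(read_length, fe - fs + 1L)
    rs <- fs + floor(stats::runif(length(idx)) * (fe - fs + 2L - len))
    straddle <- stats::runif(length(idx)) < boundary_fraction
    rs[straddle] <- pmax(1L, fs[straddle] - floor(len[straddle] / 2))
    gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(f))[idx],
      IRanges::IRanges(start = rs, width = len))
    names(gr) <- sprintf("%s_read%06d", colnames(counts)[j],
                         seq_along(gr))
    out[[j]] <- gr
  }
  out
}

#' Write single-block reads as a SAM file
#'
#' Minimal unpaired SAM records (flag 0, MAPQ 60, `*` sequence), one file per
#' library. Multi-block reads are encoded with `N` cigar gaps.
#'
#' @param reads `GRanges` (single-block reads) or `GRangesList` (blocks per
#'   read) with read names.
#' @param file Output path (`.sam`).
#' @param seqlengths Named chromosome lengths for the header.
#' @return `file`, invisibly.
#' @export
write_sam <- function(reads, file, seqlengths) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (methods::is(reads, "GRangesList")) {
    qname <- names(reads)
    chrom <- vapply(seq_along(reads), function(i)
      as.character(GenomicRanges::seqnames(reads[[i]]))[1L], "")
    pos <- vapply(seq_along(reads), function(i)
      GenomicRanges::start(reads[[i]])[1L], 1L)
    cigar <- vapply(seq_along(reads), function(i) {
      b <- reads[[i]]
      w <- GenomicRanges::width(b)
      if (length(b) == 1L) return(sprintf("%dM", w))
      gaps <- GenomicRanges::start(b)[-1L] -
        GenomicRanges::end(b)[-length(b)] - 1L
      paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
             w[length(w)], "M")
    }, "")
  } else {
    qname <- names(reads)
    chrom <- as.character(GenomicRanges::seqnames(reads))
    pos <- GenomicRanges::start(reads)
    cigar <- sprintf("%dM", GenomicRanges::width(reads))
  }
  if (length(qname))
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                       qname, chrom, as.integer(pos), cigar), con)
  invisible(file)
}
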