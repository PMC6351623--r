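#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope)`, where the slope is the fitted change in threshold
#' cycle (Ct) per log10 of input concentration. A perfect doubling per cycle
#' gives a slope of about -3.32 and `E = 2`; the slope must be negative.
#'
#' @param slope Standard-curve slope (Ct per log10 concentration).
#' @return Efficiency `E` in fold per cycle.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative")
  10^(-1 / slope)
}

#' Pfaffl efficiency-corrected relative quantification
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with
#' `dCt = Ct(control) - Ct(sample)` for the target and the reference gene
#' respectively. With both efficiencies equal to 2 this reduces to the
#' classic `2^-ddCt` form.
#'
#' @param e_target,e_ref Amplification efficiencies (fold per cycle).
#' @param dct_target,dct_ref Ct differences, control minus sample.
#' @return Fold change of the target, normalized to the reference gene.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  stopifnot(all(e_target > 1), all(e_ref > 1))
  e_target^dct_target / e_ref^dct_ref
}

#' Two-sided two-sample comparison of qPCR ratios
#'
#' Student's t test (two-tailed, pooled variance) on per-replicate ratios.
#' Two identical constant groups return `p = 1` by convention; two different
#' constant groups return `p = 0` with a warning (the t statistic is not
#' defined there).
#'
#' @param x,y Numeric vectors of per-replicate values, length >= 2 each.
#' @return List with `statistic` (t), `df` and `p.value`.
#' @export
group_compare <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 replicates per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, df = length(x) + length(y) - 2L, p.value = 1))
    warning("both groups constant but different; p reported as 0")
    return(list(statistic = Inf, df = length(x) + length(y) - 2L, p.value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Read a Ct table
#'
#' Expected columns: `assay` (e.g. spliced / unspliced primer set per
#' target), `sample`, `group`, `ct`; optional `slope` (standard-curve slope
#' per assay, constant within assay).
#'
#' @param file TSV path.
#' @return A `data.frame`.
#' @export
read_ct_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("assay", "sample", "group", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Pfaffl relative quantification of an assay against a reference gene
#'
#' Technical replicates (rows sharing `assay` and `sample`) are averaged
#' before Ct differences are formed. The control level is the mean Ct over
#' control-group samples; each sample then gets
#' `dCt = mean Ct(control) - Ct(sample)` for the target and the reference
#' assay, and the Pfaffl ratio combines them. Control samples therefore have
#' ratios scattered around 1.
#'
#' @param ct `data.frame` as from [read_ct_table()].
#' @param target,reference Assay names (the reference plays the stably
#'   expressed internal-control role).
#' @param control_group Value of `group` defining the control samples.
#' @param efficiencies Named numeric vector of per-assay efficiencies; if
#'   missing, computed from a `slope` column via [efficiency_from_slope()].
#' @return `data.frame` with one row per sample: `sample`, `group`,
#'   `dct_target`, `dct_ref`, `ratio`; attribute `p.value` holds the
#'   two-sided t test comparing ratios of each non-control group against the
#'   control group (named list).
#' @export
qpcr_analysis <- function(ct, target, reference, control_group,
                          efficiencies = NULL) {
  stopifnot(target %in% ct$assay, reference %in% ct$assay,
            control_group %in% ct$group)
  if (is.null(efficiencies)) {
    if (is.null(ct$slope)) stop("supply efficiencies or a slope column")
    sl <- tapply(ct$slope, ct$assay, function(x) x[1L])
    efficiencies <- efficiency_from_slope(sl)
  }
  agg <- stats::aggregate(ct["ct"], by = ct[c("assay", "sample", "group")],
                          FUN = mean)
  one <- function(assay) agg[agg$assay == assay, , drop = FALSE]
  tg <- one(target); rf <- one(reference)
  common <- intersect(tg$sample, rf$sample)
  tg <- tg[match(common, tg$sample), ]
  rf <- rf[match(common, rf$sample), ]
  ctrl_t <- mean(tg$ct[tg$group == control_group])
  ctrl_r <- mean(rf$ct[rf$group == control_group])
  dct_t <- ctrl_t - tg$ct
  dct_r <- ctrl_r - rf$ct
  ratio <- pfaffl_ratio(efficiencies[[target]], dct_t,
                        efficiencies[[reference]], dct_r)
  out <- data.frame(sample = common, group = tg$group,
                    dct_target = dct_t, dct_ref = dct_r, ratio = ratio,
                    stringsAsFactors = FALSE)
  pvals <- list()
  for (g in setdiff(unique(out$group), control_group))
    pvals[[g]] <- group_compare(out$ratio[out$group == g],
                                out$ratio[out$group == control_group])$p.value
  attr(out, "p.value") <- pvals
  out
}
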