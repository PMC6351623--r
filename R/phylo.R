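#' Read a rooted species tree from a newick file
#'
#' @param file Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string instead of a file.
#' @return An [ape::read.tree()] `phylo` object, validated to be rooted and
#'   binary-labelled: duplicate tip labels or an unrooted tree are hard
#'   errors.
#' @export
read_species_tree <- function(file = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; supply a rooted species tree")
  tree
}

# children of each node, from the edge matrix
.children <- function(tree) {
  n_node <- max(tree$edge)
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

.presence_vector <- function(tree, presence) {
  tips <- tree$tip.label
  if (is.character(presence)) {
    unknown <- setdiff(presence, tips)
    if (length(unknown))
      stop("present species not in tree: ", paste(unknown, collapse = ", "))
    presence <- tips %in% presence
  } else {
    if (is.null(names(presence)) || !all(tips %in% names(presence)))
      stop("presence vector must be named by the tree's tip labels")
    presence <- as.logical(presence[tips])
  }
  stats::setNames(presence, tips)
}

#' Minimal gene losses under Dollo parsimony
#'
#' Under the Dollo model the character (gene presence) arises once, at the
#' root, and can only be lost. The minimal reconstruction places one loss on
#' each edge leading to a maximal subtree whose tips all lack the gene.
#'
#' @param tree Rooted `phylo` tree.
#' @param presence Character vector of present tip labels, or a named logical
#'   over all tips.
#' @return List with `n_losses`, and `loss_clades`: a list, one element per
#'   loss edge, of the tip labels of the clade lost.
#' @export
dollo_min_losses <- function(tree, presence) {
  pres <- .presence_vector(tree, presence)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  if (all(!pres)) {
    message("character absent from every tip; counting one loss at the root")
    return(list(n_losses = 1L, loss_clades = list(tree$tip.label)))
  }
  n_node <- max(tree$edge)
  all_absent <- logical(n_node)
  all_absent[seq_len(n_tip)] <- !pres
  ch <- .children(tree)
  all_absent[seq.int(root, n_node)] <- NA
  # node ids carry no order guarantee; resolve by repeated passes (trees are small)
  todo <- seq.int(n_tip + 1L, n_node)
  while (length(todo)) {
    done <- logical(length(todo))
    for (i in seq_along(todo)) {
      v <- todo[i]
      kids <- ch[[v]]
      vals <- all_absent[kids]
      if (!anyNA(vals)) {
        all_absent[v] <- all(vals)
        done[i] <- TRUE
      }
    }
    if (!any(done)) stop("malformed tree edges")
    todo <- todo[!done]
  }
  loss_child <- tree$edge[, 2L][all_absent[tree$edge[, 2L]] &
                                !all_absent[tree$edge[, 1L]]]
  clades <- lapply(loss_child, function(v) {
    if (v <= n_tip) tree$tip.label[v]
    else ape::extract.clade(tree, v)$tip.label
  })
  list(n_losses = length(loss_child), loss_clades = clades)
}

#' Minimal state changes under Fitch parsimony
#'
#' Small-parsimony count for a binary character via the classic post-order
#' set intersection/union pass; gains and losses both allowed. Serves as an
#' unrestricted cross-check on [dollo_min_losses()] (the Fitch count never
#' exceeds the Dollo loss count).
#'
#' @inheritParams dollo_min_losses
#' @return Integer: minimal number of state changes on the tree.
#' @export
fitch_min_changes <- function(tree, presence) {
  pres <- .presence_vector(tree, presence)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  # state sets encoded as bitmasks: 1 = absent, 2 = present, 3 = both
  sets <- integer(n_node)
  sets[seq_len(n_tip)] <- ifelse(pres, 2L, 1L)
  ch <- .children(tree)
  changes <- 0L
  todo <- seq.int(n_tip + 1L, n_node)
  while (length(todo)) {
    done <- logical(length(todo))
    for (i in seq_along(todo)) {
      v <- todo[i]
      vals <- sets[ch[[v]]]
      if (all(vals > 0L)) {
        s <- Reduce(bitwAnd, vals)
        if (s == 0L) {
          s <- Reduce(bitwOr, vals)
          changes <- changes + 1L
        }
        sets[v] <- s
        done[i] <- TRUE
      }
    }
    if (!any(done)) stop("malformed tree edges")
    todo <- todo[!done]
  }
  changes
}

#' Count species carrying a full factor set
#'
#' @param traits `data.frame` with a `species` column, factor columns coded
#'   `"+"` / `"-"`, and optional annotation columns (e.g. `group`, `family`).
#' @param factors Character vector of factor column names; an unknown factor
#'   is an error.
#' @param clade Optional value of `clade_column` to restrict the species set
#'   (e.g. `"Saccharomycotina"`).
#' @param clade_column Column holding the clade annotation (default
#'   `"group"`).
#' @return List with `count` (species carrying every factor in `factors`),
#'   `species` (their names), and `pairwise`, the factors-by-factors matrix
#'   of co-occurrence counts within the selected species.
#' @export
package_cooccurrence <- function(traits, factors, clade = NULL,
                                 clade_column = "group") {
  unknown <- setdiff(factors, names(traits))
  if (length(unknown))
    stop("unknown factor: ", paste(unknown, collapse = ", "))
  if (!is.null(clade)) {
    if (!clade_column %in% names(traits))
      stop("no '", clade_column, "' column in trait table")
    traits <- traits[traits[[clade_column]] == clade, , drop = FALSE]
  }
  if (nrow(traits) == 0L)
    return(list(count = 0L, species = character(0),
                pairwise = matrix(0L, length(factors), length(factors),
                                  dimnames = list(factors, factors))))
  pm <- sapply(factors, function(f) traits[[f]] == "+")
  pm <- matrix(pm, nrow = nrow(traits),
               dimnames = list(traits$species, factors))
  all_present <- rowSums(pm) == length(factors)
  pairwise <- crossprod(pm)
  mode(pairwise) <- "integer"
  list(count = sum(all_present),
       species = traits$species[all_present],
       pairwise = pairwise)
}

#' Packaged EJC presence/absence survey
#'
#' A curated encoding of a comparative survey of exon junction complex (EJC)
#' core components (MAGO, Y14) and peripheral factors (UPF3, PYM, Aly/REF,
#' IBP160) across Ascomycota and Basidiomycota species, together with a
#' family-level species tree. The MAGO/Y14/PYM calls follow the survey's
#' species-level reporting; the peripheral-factor calls summarize its
#' clade-level statements. See the package data files
#' `extdata/ejc_presence_absence.tsv` and `extdata/ejc_species_tree.nwk`.
#'
#' @return List with `traits` (`data.frame`) and `tree` (`phylo`).
#' @export
ejc_survey <- function() {
  tf <- system.file("extdata", "ejc_presence_absence.tsv", package = "intronr",
                    mustWork = TRUE)
  nf <- system.file("extdata", "ejc_species_tree.nwk", package = "intronr",
                    mustWork = TRUE)
  traits <- utils::read.table(tf, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
  tree <- read_species_tree(nf)
  stopifnot(setequal(tree$tip.label, traits$species))
  list(traits = traits, tree = tree)
}
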